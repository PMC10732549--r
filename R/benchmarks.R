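# Evaluation-dataset compilation rules and retrieval / regression metrics.

#' Compile a protein-centric evaluation dataset
#'
#' Keeps interactions whose protein has at least `min_compounds` distinct
#' associated compounds (the similar-compound-retrieval design: 20 by
#' default). Never creates records; output is a subset of the input.
#'
#' @param records data.frame of interaction records (see
#'   [read_annotation_db()] for columns).
#' @param min_compounds threshold (default 20).
#' @return an `eval_dataset`: `records`, `kind`, `n_kept`/`n_dropped`
#'   protein counts, and the threshold used.
#' @export
compile_ds1 <- function(records, min_compounds = 20L) {
  counts <- tapply(records$compound_id, records$target_id,
                   function(x) length(unique(x)))
  keep_prot <- names(counts)[counts >= min_compounds]
  out <- records[records$target_id %in% keep_prot, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(records = out, kind = "DS-I-like",
                 n_kept = length(keep_prot),
                 n_dropped = length(counts) - length(keep_prot),
                 compiled_params = list(min_compounds = min_compounds)),
            class = "eval_dataset")
}

#' Compile a compound-centric evaluation dataset
#'
#' Keeps interactions whose compound has at least `min_targets` distinct
#' targets (the target-identification design: 5 by default). Idempotent.
#'
#' @param records interaction records.
#' @param min_targets threshold (default 5).
#' @return an `eval_dataset` (kind `"DS-II-like"`).
#' @export
compile_ds2 <- function(records, min_targets = 5L) {
  counts <- tapply(records$target_id, records$compound_id,
                   function(x) length(unique(x)))
  keep_cpd <- names(counts)[counts >= min_targets]
  out <- records[records$compound_id %in% keep_cpd, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(records = out, kind = "DS-II-like",
                 n_kept = length(keep_cpd),
                 n_dropped = length(counts) - length(keep_cpd),
                 compiled_params = list(min_targets = min_targets)),
            class = "eval_dataset")
}

#' @export
print.eval_dataset <- function(x, ...) {
  cat(sprintf("<eval_dataset> %s: %d records, %d entities kept / %d dropped\n",
              x$kind, nrow(x$records), x$n_kept, x$n_dropped))
  invisible(x)
}

#' Seeded train/test split
#'
#' Shuffles with the given seed and takes `floor(n * ratio)` for training;
#' the remainder is the test set. The two parts are disjoint and cover the
#' input.
#'
#' @param x vector (or list) to split.
#' @param ratio train fraction in (0,1), default 0.8.
#' @param seed integer seed.
#' @return `list(train =, test =)` of elements of `x`.
#' @export
split_dataset <- function(x, ratio = 0.8, seed = 1L) {
  n <- length(x)
  if (n < 2L) stopf("need at least 2 elements to split, got %d", n)
  if (ratio <= 0 || ratio >= 1) stopf("ratio must be in (0,1)")
  set.seed(seed)
  ord <- sample.int(n)
  ntr <- floor(n * ratio)
  list(train = x[ord[seq_len(ntr)]], test = x[ord[(ntr + 1L):n]])
}

#' Set-retrieval metrics
#'
#' recall = |P intersect T| / |T|; precision = |P intersect T| / |P| (0 for
#' empty P); F = 2PR/(P+R) (0 when both are 0).
#'
#' @param predicted character vector (or set) of predicted ids.
#' @param truth nonempty character vector of true ids.
#' @return list `recall`, `precision`, `f_score`, `n_predicted`, `n_truth`.
#' @export
score_retrieval <- function(predicted, truth) {
  truth <- unique(as.character(truth))
  if (length(truth) == 0L) stopf("truth set must be nonempty")
  predicted <- unique(as.character(predicted))
  tp <- length(intersect(predicted, truth))
  recall <- tp / length(truth)
  precision <- if (length(predicted) == 0L) 0 else tp / length(predicted)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(recall = recall, precision = precision, f_score = f,
       n_predicted = length(predicted), n_truth = length(truth))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive outscores
#' a random negative, ties counted half (average ranks).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Pearson correlation with validation
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return product-moment correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 3L) stopf("need at least 3 points")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance input")
  cor(x, y, method = "pearson")
}

#' Published benchmark-dataset summary totals
#'
#' Totals of the three affinity benchmarks the interaction network is
#' conventionally trained on (compound count, protein count, interaction
#' count). Used to recompute the per-compound / per-protein average
#' interaction counts.
#'
#' @return data.frame `dataset`, `n_compounds`, `n_proteins`,
#'   `n_interactions`.
#' @export
benchmark_dataset_stats <- function() {
  data.frame(
    dataset = c("PDBbind", "Davis", "Metz"),
    n_compounds = c(2509L, 68L, 1471L),
    n_proteins = c(10251L, 379L, 172L),
    n_interactions = c(13311L, 9125L, 35307L),
    stringsAsFactors = FALSE)
}

#' Average interactions per compound and per protein
#'
#' @param stats a data.frame as returned by [benchmark_dataset_stats()].
#' @param digits rounding (default 1, matching the usual reporting).
#' @return `stats` with `per_compound` and `per_protein` columns appended.
#' @export
interaction_averages <- function(stats = benchmark_dataset_stats(), digits = 1L) {
  stats$per_compound <- round(stats$n_interactions / stats$n_compounds, digits)
  stats$per_protein <- round(stats$n_interactions / stats$n_proteins, digits)
  stats
}
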