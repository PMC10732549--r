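# Attention-based compound-protein interaction network.
#
# Architecture (all sizes in train_config()):
#   protein:   BLOSUM62+PE -> three 1D convolutions (same padding, ReLU)
#   compound:  atom features -> two graph convolutions (bond-order-weighted
#              sum-pooling message passing, ReLU) -> per-fragment mean pooling
#   both sides -> five feature-wise fully connected ReLU layers
#   cross-attention: fragments attend over residues (scaled dot product,
#              softmax over residues); context = attention %*% residues
#   output:    joint = fragment-embedding * context (elementwise), mean over
#              fragments, linear head -> affinity (pKd)
#   display score = logistic squashing of pKd centred at 6.
#
# Training minimizes mean squared error on affinity with Adam on
# mini-batches. Forward, backward, and the optimizer are implemented here in
# plain matrix algebra; a gradient-check test validates the backward pass
# against central differences.

#' Training / architecture configuration
#'
#' @param batch_size mini-batch size (default 8).
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs training epochs.
#' @param seed integer seed fixing initialization, the train/test split and
#'   batch shuffling.
#' @param split_ratio train fraction of the 80/20-style split.
#' @param hidden hidden width of every layer (default 128).
#' @param kernel 1D convolution kernel size (default 7).
#' @param d_pe positional-encoding channels (default 8).
#' @param n_pconv,n_gconv,n_fc protein conv / graph conv / feature-wise FC
#'   layer counts (defaults 3, 2, 5).
#' @return a `cpi_config` list.
#' @export
train_config <- function(batch_size = 8L, lr = 1e-4, epochs = 50L, seed = 1L,
                         split_ratio = 0.8, hidden = 128L, kernel = 7L,
                         d_pe = 8L, n_pconv = 3L, n_gconv = 2L, n_fc = 5L) {
  if (split_ratio <= 0 || split_ratio >= 1) stopf("split_ratio must be in (0,1)")
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 split_ratio = split_ratio, hidden = as.integer(hidden),
                 kernel = as.integer(kernel), d_pe = as.integer(d_pe),
                 n_pconv = as.integer(n_pconv), n_gconv = as.integer(n_gconv),
                 n_fc = as.integer(n_fc)),
            class = "cpi_config")
}

#' Initialize network parameters
#'
#' He-scaled normal initialization, fully determined by the seed.
#'
#' @param cfg a [train_config()].
#' @return named flat list of weight matrices/vectors (a `cpi_params`).
#' @export
cpi_init <- function(cfg = train_config()) {
  set.seed(cfg$seed)
  h <- cfg$hidden; w <- cfg$kernel
  d_in <- 20L + cfg$d_pe
  p <- atom_feature_width()
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  par <- list()
  din <- d_in
  for (l in seq_len(cfg$n_pconv)) {
    par[[sprintf("pconv%d_W", l)]] <- he(w * din, h)
    par[[sprintf("pconv%d_b", l)]] <- numeric(h)
    din <- h
  }
  din <- p
  for (l in seq_len(cfg$n_gconv)) {
    par[[sprintf("gconv%d_Ws", l)]] <- he(din, h)
    par[[sprintf("gconv%d_Wn", l)]] <- he(din, h)
    par[[sprintf("gconv%d_b", l)]] <- numeric(h)
    din <- h
  }
  for (side in c("pfc", "cfc"))
    for (l in seq_len(cfg$n_fc)) {
      par[[sprintf("%s%d_W", side, l)]] <- he(h, h)
      par[[sprintf("%s%d_b", side, l)]] <- numeric(h)
    }
  par$out_v <- rnorm(h, sd = sqrt(1 / h))
  par$out_b <- 6  # pKd scale prior: initialize at the squashing centre
  structure(par, class = "cpi_params", cfg = cfg)
}

# --- primitive layers ------------------------------------------------------

# im2col for 1D same-padding convolution over an L x d matrix
im2col1d <- function(X, w) {
  L <- nrow(X); d <- ncol(X)
  pad <- (w - 1L) %/% 2L
  Xp <- rbind(matrix(0, pad, d), X, matrix(0, w - 1L - pad, d))
  idx <- outer(seq_len(L), seq_len(w) - 1L, `+`)   # L x w row indices into Xp
  out <- matrix(0, L, w * d)
  for (q in seq_len(w))
    out[, ((q - 1L) * d + 1L):(q * d)] <- Xp[idx[, q], , drop = FALSE]
  out
}

# scatter-add of column gradients back to the (unpadded) input
col2im1d <- function(dCol, L, d, w) {
  pad <- (w - 1L) %/% 2L
  dXp <- matrix(0, L + w - 1L, d)
  idx <- outer(seq_len(L), seq_len(w) - 1L, `+`)
  for (q in seq_len(w)) {
    block <- dCol[, ((q - 1L) * d + 1L):(q * d), drop = FALSE]
    tgt <- idx[, q]
    dXp[tgt, ] <- dXp[tgt, ] + block
  }
  dXp[(pad + 1L):(pad + L), , drop = FALSE]
}

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Network forward pass
#'
#' @param par `cpi_params`.
#' @param penc protein encoding from [encode_protein()].
#' @param cenc compound encoding from [encode_compound()].
#' @param keep_cache retain intermediates for the backward pass.
#' @return a `cpi_prediction`: `affinity` (pKd), `score` in \[0,1\],
#'   `attention` (F x L, rows sum to 1), `fragment_scores` (per-fragment
#'   additive share of the affinity), plus a cache when requested.
#' @export
cpi_forward <- function(par, penc, cenc, keep_cache = FALSE) {
  cfg <- attr(par, "cfg")
  if (ncol(penc) != 20L + cfg$d_pe)
    stopf("protein encoding has %d columns; model expects %d", ncol(penc), 20L + cfg$d_pe)
  if (ncol(cenc$atom_features) != atom_feature_width())
    stopf("compound encoding width mismatch")
  h <- cfg$hidden; w <- cfg$kernel
  cache <- list(pcols = list(), pacts = list(penc), gacts = list(cenc$atom_features))
  # protein conv stack
  X <- penc
  for (l in seq_len(cfg$n_pconv)) {
    Col <- im2col1d(X, w)
    Z <- sweep(Col %*% par[[sprintf("pconv%d_W", l)]], 2L,
               par[[sprintf("pconv%d_b", l)]], `+`)
    X <- pmax(Z, 0)
    cache$pcols[[l]] <- Col
    cache$pacts[[l + 1L]] <- X
  }
  # compound graph conv stack
  A <- cenc$adj
  G <- cenc$atom_features
  cache$gmsg <- list()
  for (l in seq_len(cfg$n_gconv)) {
    AG <- A %*% G
    Z <- sweep(G %*% par[[sprintf("gconv%d_Ws", l)]] +
               AG %*% par[[sprintf("gconv%d_Wn", l)]], 2L,
               par[[sprintf("gconv%d_b", l)]], `+`)
    cache$gmsg[[l]] <- AG
    G <- pmax(Z, 0)
    cache$gacts[[l + 1L]] <- G
  }
  Frag0 <- cenc$frag_map %*% G
  # feature-wise FC stacks
  R <- X; cache$pfc <- list(R)
  for (l in seq_len(cfg$n_fc)) {
    R <- pmax(sweep(R %*% par[[sprintf("pfc%d_W", l)]], 2L,
                    par[[sprintf("pfc%d_b", l)]], `+`), 0)
    cache$pfc[[l + 1L]] <- R
  }
  Fq <- Frag0; cache$cfc <- list(Fq)
  for (l in seq_len(cfg$n_fc)) {
    Fq <- pmax(sweep(Fq %*% par[[sprintf("cfc%d_W", l)]], 2L,
                     par[[sprintf("cfc%d_b", l)]], `+`), 0)
    cache$cfc[[l + 1L]] <- Fq
  }
  # cross-attention: fragments over residues
  S <- (Fq %*% t(R)) / sqrt(h)
  Att <- softmax_rows(S)
  Ctx <- Att %*% R
  J <- Fq * Ctx
  j <- colMeans(J)
  affinity <- sum(par$out_v * j) + par$out_b
  # per-fragment share: affinity - out_b = mean_f v . (Fq_f * Ctx_f)
  frag_scores <- as.numeric((J %*% par$out_v) / nrow(J))
  pred <- structure(
    list(affinity = affinity, score = 1 / (1 + exp(-(affinity - 6))),
         attention = Att, fragment_scores = frag_scores,
         n_fragments = nrow(Fq), n_residues = nrow(R)),
    class = "cpi_prediction")
  if (keep_cache) {
    cache$S <- S; cache$Att <- Att; cache$Ctx <- Ctx; cache$J <- J
    cache$j <- j; cache$Fq <- Fq; cache$R <- R; cache$Frag0 <- Frag0
    cache$cenc <- cenc
    pred$cache <- cache
  }
  pred
}

#' @export
print.cpi_prediction <- function(x, ...) {
  cat(sprintf("<cpi_prediction> affinity (pKd) = %.3f, score = %.3f, attention %d x %d\n",
              x$affinity, x$score, x$n_fragments, x$n_residues))
  invisible(x)
}

# backward pass: gradient of (daff * affinity) w.r.t. all parameters.
# Returns a flat list mirroring par; also used by the gradient-check test.
cpi_backward <- function(par, pred, daff = 1) {
  cfg <- attr(par, "cfg")
  h <- cfg$hidden; w <- cfg$kernel
  cc <- pred$cache
  g <- list()
  Fn <- nrow(cc$Fq)
  g$out_v <- daff * cc$j
  g$out_b <- daff
  dJ <- matrix(rep(daff * par$out_v / Fn, each = Fn), Fn)
  dFq <- dJ * cc$Ctx
  dCtx <- dJ * cc$Fq
  dAtt <- dCtx %*% t(cc$R)
  dR <- t(cc$Att) %*% dCtx
  rs <- rowSums(dAtt * cc$Att)
  dS <- cc$Att * (dAtt - rs)
  dFq <- dFq + (dS %*% cc$R) / sqrt(h)
  dR <- dR + (t(dS) %*% cc$Fq) / sqrt(h)
  # FC stacks backward
  for (l in rev(seq_len(cfg$n_fc))) {
    act <- cc$cfc[[l + 1L]]
    dpre <- dFq * (act > 0)
    g[[sprintf("cfc%d_W", l)]] <- t(cc$cfc[[l]]) %*% dpre
    g[[sprintf("cfc%d_b", l)]] <- colSums(dpre)
    dFq <- dpre %*% t(par[[sprintf("cfc%d_W", l)]])
  }
  for (l in rev(seq_len(cfg$n_fc))) {
    act <- cc$pfc[[l + 1L]]
    dpre <- dR * (act > 0)
    g[[sprintf("pfc%d_W", l)]] <- t(cc$pfc[[l]]) %*% dpre
    g[[sprintf("pfc%d_b", l)]] <- colSums(dpre)
    dR <- dpre %*% t(par[[sprintf("pfc%d_W", l)]])
  }
  # fragment pooling
  dG <- t(cc$cenc$frag_map) %*% dFq
  A <- cc$cenc$adj
  for (l in rev(seq_len(cfg$n_gconv))) {
    act <- cc$gacts[[l + 1L]]
    dpre <- dG * (act > 0)
    Gin <- cc$gacts[[l]]
    g[[sprintf("gconv%d_Ws", l)]] <- t(Gin) %*% dpre
    g[[sprintf("gconv%d_Wn", l)]] <- t(cc$gmsg[[l]]) %*% dpre
    g[[sprintf("gconv%d_b", l)]] <- colSums(dpre)
    dG <- dpre %*% t(par[[sprintf("gconv%d_Ws", l)]]) +
      A %*% (dpre %*% t(par[[sprintf("gconv%d_Wn", l)]]))
  }
  dX <- dR
  for (l in rev(seq_len(cfg$n_pconv))) {
    act <- cc$pacts[[l + 1L]]
    dpre <- dX * (act > 0)
    g[[sprintf("pconv%d_W", l)]] <- t(cc$pcols[[l]]) %*% dpre
    g[[sprintf("pconv%d_b", l)]] <- colSums(dpre)
    dCol <- dpre %*% t(par[[sprintf("pconv%d_W", l)]])
    dX <- col2im1d(dCol, nrow(act), ncol(cc$pacts[[l]]), w)
  }
  g
}

# --- training --------------------------------------------------------------

#' Train the interaction network
#'
#' @param dataset list of examples, each
#'   `list(mol = <mol_graph>, protein = <protein_seq|string>, affinity =
#'   <pKd>)`; at least `2 * batch_size` examples.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return a `cpi_model`: `params`, `cfg`, `log` (per-epoch train/test MSE),
#'   and the train/test split indices.
#' @export
cpi_train <- function(dataset, cfg = train_config(), verbose = FALSE) {
  n <- length(dataset)
  if (n < 2L * cfg$batch_size)
    stopf("need at least %d examples, got %d", 2L * cfg$batch_size, n)
  y <- vapply(dataset, function(d) d$affinity, 0)
  if (any(!is.finite(y))) stopf("non-finite affinity in dataset")
  enc <- precompute_encodings(dataset, cfg)
  sp <- split_dataset(seq_len(n), ratio = cfg$split_ratio, seed = cfg$seed)
  tr <- sp$train; te <- sp$test
  par <- cpi_init(cfg)
  opt <- adam_state(par)
  log <- data.frame(epoch = integer(), train_mse = numeric(), test_mse = numeric())
  set.seed(derive_seed(cfg$seed, 777L))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_losses <- numeric()
    for (bt in batches) {
      gsum <- NULL
      bloss <- 0
      for (i in bt) {
        pred <- cpi_forward(par, enc$prot[[enc$pidx[i]]], enc$comp[[i]],
                            keep_cache = TRUE)
        err <- pred$affinity - y[i]
        bloss <- bloss + err^2
        gi <- cpi_backward(par, pred, daff = 2 * err / length(bt))
        gsum <- if (is.null(gsum)) gi
                else mapply(`+`, gsum, gi[names(gsum)], SIMPLIFY = FALSE)
      }
      bloss <- bloss / length(bt)
      if (!is.finite(bloss))
        stopf("training aborted: non-finite loss at epoch %d", ep)
      ep_losses <- c(ep_losses, bloss)
      upd <- adam_step(par, gsum, opt, cfg$lr)
      par <- upd$par; opt <- upd$opt
    }
    test_mse <- mean(vapply(te, function(i) {
      (cpi_forward(par, enc$prot[[enc$pidx[i]]], enc$comp[[i]])$affinity - y[i])^2
    }, 0))
    log <- rbind(log, data.frame(epoch = ep, train_mse = mean(ep_losses),
                                 test_mse = test_mse))
    if (verbose)
      message(sprintf("epoch %3d  train MSE %.4f  test MSE %.4f",
                      ep, mean(ep_losses), test_mse))
  }
  structure(list(params = par, cfg = cfg, log = log, train_idx = tr,
                 test_idx = te),
            class = "cpi_model")
}

#' @export
print.cpi_model <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<cpi_model> hidden %d, %d epochs; final train MSE %.4f, test MSE %.4f\n",
              x$cfg$hidden, nrow(x$log), last$train_mse, last$test_mse))
  invisible(x)
}

precompute_encodings <- function(dataset, cfg) {
  seqs <- vapply(dataset, function(d)
    if (inherits(d$protein, "protein_seq")) d$protein$sequence else d$protein, "")
  useq <- unique(seqs)
  prot <- lapply(useq, encode_protein, d_pe = cfg$d_pe)
  comp <- lapply(dataset, function(d) encode_compound(d$mol))
  list(prot = prot, pidx = match(seqs, useq), comp = comp)
}

adam_state <- function(par) {
  list(m = lapply(par, function(x) x * 0), v = lapply(par, function(x) x * 0),
       t = 0L)
}

adam_step <- function(par, grad, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(par)) {
    gnm <- grad[[nm]]
    if (is.null(gnm)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gnm
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gnm^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, opt = opt)
}

#' Predict affinity for one compound-protein pair
#'
#' @param model a `cpi_model` (or bare `cpi_params`).
#' @param mol a `mol_graph`.
#' @param protein a `protein_seq` or string.
#' @return a `cpi_prediction` (see [cpi_forward()]) carrying the fragment
#'   partition used.
#' @export
cpi_predict <- function(model, mol, protein) {
  par <- if (inherits(model, "cpi_model")) model$params else model
  cfg <- attr(par, "cfg")
  part <- fragment_molecule(mol)
  pred <- cpi_forward(par, encode_protein(protein, d_pe = cfg$d_pe),
                      encode_compound(mol, part))
  pred$partition <- part
  pred
}

#' Rank compound fragments by their attention-derived importance
#'
#' The default statistic is each fragment's additive share of the predicted
#' affinity: `sum_l attention[f, l] * salience[f, l]` with
#' `salience[f, l] = v . (frag_f * residue_l)`; `"logit_mass"` ranks by
#' attention concentration (mean log attention weight) instead.
#'
#' @param pred a `cpi_prediction` from [cpi_predict()].
#' @param partition the matching `fragment_partition` (defaults to the one
#'   stored in `pred`).
#' @param statistic `"contribution"` (default) or `"logit_mass"`.
#' @return data.frame `fragment`, `atoms` (list column), `statistic`,
#'   `weight` (softmax-normalized), `rank` (ties broken by fragment index).
#' @export
attention_fragments <- function(pred, partition = pred$partition,
                                statistic = c("contribution", "logit_mass")) {
  statistic <- match.arg(statistic)
  if (is.null(partition)) stopf("no fragment partition supplied")
  f <- length(partition$clusters)
  if (nrow(pred$attention) != f)
    stopf("attention has %d rows but partition has %d fragments",
          nrow(pred$attention), f)
  stat <- switch(statistic,
                 contribution = pred$fragment_scores * f,  # undo the 1/F pooling
                 logit_mass = {
                   # recover relative logits from the softmax rows
                   rowMeans(log(pmax(pred$attention, 1e-300)))
                 })
  wex <- exp(stat - max(stat))
  out <- data.frame(fragment = seq_len(f), statistic = stat,
                    weight = wex / sum(wex))
  out$atoms <- partition$clusters
  out <- out[order(-out$statistic, out$fragment), ]
  out$rank <- seq_len(f)
  rownames(out) <- NULL
  out[, c("fragment", "atoms", "statistic", "weight", "rank")]
}

#' Save / load a model checkpoint
#'
#' Versioned RDS archive holding weights, configuration, and the training
#' log.
#'
#' @param model a `cpi_model`.
#' @param path file path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the
#'   `cpi_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "driftr-checkpoint", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "driftr-checkpoint"))
    stopf("not a driftr checkpoint: %s", path)
  x$model
}
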