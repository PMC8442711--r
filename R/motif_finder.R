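# Ungapped motif discovery by expectation maximisation, in the spirit of
# MEME's any-number-of-repeats model: every width-w window of every peptide
# is either an instance of a single position weight matrix (PWM) or drawn
# from a background residue distribution; EM re-estimates the PWM, and a
# deterministic seeding scheme restarts EM from the most self-similar
# windows. This is a self-contained simplification, not numerically
# identical to the MEME suite.

.MOTIF_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Integer-encode all width-w windows of a peptide set. X (index 21) scores
# as background wherever it appears. Returns list(W = nwin x w integer
# matrix, peptide = source index, offset = 0-based window offset).
.window_matrix <- function(peptides, width) {
  rows <- list(); pep_idx <- integer(0); offs <- integer(0)
  for (p in seq_along(peptides)) {
    aa <- strsplit(peptides[p], "", fixed = TRUE)[[1]]
    code <- match(aa, c(.MOTIF_ALPHABET, "X"))
    if (anyNA(code)) {
      stop(sprintf("illegal residue in peptide %d", p), call. = FALSE)
    }
    L <- length(code)
    if (L < width) next
    for (s in 0:(L - width)) {
      rows[[length(rows) + 1L]] <- code[(s + 1):(s + width)]
      pep_idx <- c(pep_idx, p); offs <- c(offs, s)
    }
  }
  list(W = do.call(rbind, rows), peptide = pep_idx, offset = offs)
}

# Pooled residue frequencies of the input peptides over the 20 canonical
# residues (X excluded), with a small floor so no residue has zero mass.
.pooled_background <- function(peptides) {
  aa <- unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(aa, levels = .MOTIF_ALPHABET))
  freq <- (as.numeric(counts) + 0.5) / (sum(counts) + 10)
  stats::setNames(freq / sum(freq), .MOTIF_ALPHABET)
}

# Sum of log-probabilities of each window row under a w x 21 log-matrix
# (column 21 = X).
.score_windows <- function(W, logmat) {
  s <- numeric(nrow(W))
  for (j in seq_len(ncol(W))) s <- s + logmat[j, W[, j]]
  s
}

#' Discover an ungapped motif by EM
#'
#' Two-component mixture over all width-`width` windows: motif (PWM) versus
#' background. The E-step computes per-window posterior responsibilities;
#' the M-step re-estimates the PWM from responsibility-weighted residue
#' counts with pseudocount 0.1 and the mixing weight from the mean
#' responsibility. EM restarts from the `n_seeds` most self-similar seed
#' windows (windows that agree with many other windows at half their
#' positions or more) and the highest final log-likelihood model is
#' returned. The whole procedure is deterministic given its inputs and
#' `seed`.
#'
#' @param peptides amino-acid strings (at least 5, each at least `width`
#'   long).
#' @param width motif width (>= 4).
#' @param n_seeds number of EM restarts from ranked seed windows.
#' @param max_iter,tol EM stopping rule (log-likelihood improvement).
#' @param pseudocount added to every weighted residue count in the M-step.
#' @param seed RNG seed (the default procedure draws no random numbers, but
#'   the seed is fixed so future stochastic options stay reproducible).
#' @param label motif label carried in the model (e.g. "A").
#' @return object of class `motif_model`: `label`, `width`, `pwm`
#'   (width x 20, rows sum to 1), `background` (20-vector), `logodds`
#'   (log2(pwm/background)), `consensus`, `info_per_col` (bits),
#'   `loglik` (final EM objective), `loglik_trace` (per-iteration EM
#'   objective: the log-likelihood penalised by the Dirichlet pseudocount
#'   prior, which is the quantity EM increases monotonically), `lambda`.
#' @export
discover_motif <- function(peptides, width, n_seeds = 20, max_iter = 100,
                           tol = 1e-6, pseudocount = 0.1, seed = 1,
                           label = "A") {
  stopifnot(width >= 4)
  if (length(peptides) < 5) {
    stop("discover_motif(): need at least 5 peptides", call. = FALSE)
  }
  if (min(nchar(peptides)) < width) {
    stop("discover_motif(): width exceeds the shortest peptide", call. = FALSE)
  }
  set.seed(seed)
  wm <- .window_matrix(peptides, width)
  W <- wm$W
  nwin <- nrow(W)
  bg <- .pooled_background(peptides)
  logbg_ext <- c(log(bg), 0)  # X scores 0 under background too
  logP_bg <- .score_windows(W, matrix(rep(logbg_ext, each = width),
                                      nrow = width))

  # Seed ranking: pairwise position-agreement between windows.
  H <- matrix(0L, nwin, nwin)
  for (j in seq_len(width)) H <- H + outer(W[, j], W[, j], "==")
  strong <- colSums(H >= ceiling(width / 2))
  sumH <- colSums(H)
  seed_order <- order(-strong, -sumH, seq_len(nwin))
  seeds <- seed_order[seq_len(min(n_seeds, nwin))]

  best <- NULL
  for (s in seeds) {
    fit <- .em_fit(W, logP_bg, seed_window = W[s, ], bg = bg,
                   max_iter = max_iter, tol = tol, pseudocount = pseudocount)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  pwm <- best$pwm
  dimnames(pwm) <- list(NULL, .MOTIF_ALPHABET)
  logodds <- log2(sweep(pwm, 2, bg, "/"))
  consensus <- paste(.MOTIF_ALPHABET[apply(pwm, 1, which.max)], collapse = "")
  info <- apply(pwm, 1, function(p) sum(p * log2(p / bg)))
  structure(list(label = label, width = width, pwm = pwm,
                 background = bg, logodds = logodds, consensus = consensus,
                 info_per_col = info, loglik = best$loglik,
                 loglik_trace = best$trace, lambda = best$lambda),
            class = "motif_model")
}

.em_fit <- function(W, logP_bg, seed_window, bg, max_iter, tol, pseudocount) {
  width <- ncol(W)
  nwin <- nrow(W)
  # initial PWM: 0.5 on the seed residue, remainder spread evenly
  pwm <- matrix(0.5 / 19, width, 20)
  for (j in seq_len(width)) {
    r <- seed_window[j]
    if (r <= 20) pwm[j, r] <- 0.5 else pwm[j, ] <- 1 / 20
  }
  lambda <- 0.05
  prev <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    logmat <- cbind(log(pwm), 0)
    logmat[, 21] <- 0  # X cancels against background
    logP_m <- .score_windows(W, logmat)
    # stable posterior and log-likelihood
    a <- log(lambda) + logP_m
    b <- log1p(-lambda) + logP_bg
    m <- pmax(a, b)
    # the pseudocount acts as a Dirichlet prior on PWM rows, so the monotone
    # EM objective is the penalised (MAP) log-likelihood
    ll <- sum(m + log(exp(a - m) + exp(b - m))) +
      pseudocount * sum(log(pwm))
    if (ll < prev - 1e-8) {
      stop("discover_motif(): EM objective decreased — internal error",
           call. = FALSE)
    }
    trace <- c(trace, ll)
    z <- 1 / (1 + exp(b - a))
    # M-step
    new_pwm <- matrix(pseudocount, width, 20)
    for (j in seq_len(width)) {
      canonical <- W[, j] <= 20
      cnt <- rowsum(z[canonical], group = W[canonical, j])
      new_pwm[j, as.integer(rownames(cnt))] <-
        new_pwm[j, as.integer(rownames(cnt))] + cnt[, 1]
    }
    pwm <- new_pwm / rowSums(new_pwm)
    lambda <- mean(z)  # z is strictly inside (0,1), so lambda is too
    if (is.finite(prev) && ll - prev < tol) { prev <- ll; break }
    prev <- ll
  }
  list(pwm = pwm, loglik = prev, trace = trace, lambda = lambda)
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s: width %d, consensus %s, %.2f bits/col\n",
              x$label, x$width, x$consensus, mean(x$info_per_col)))
  invisible(x)
}

#' Motif discovery over a range of widths
#'
#' Runs [discover_motif()] at each width and keeps the model with the
#' highest mean information content per column.
#'
#' @inheritParams discover_motif
#' @param widths integer vector of widths to try (default 8:20, clipped to
#'   the shortest peptide).
#' @return the selected `motif_model`.
#' @export
discover_motif_sweep <- function(peptides, widths = 8:20, n_seeds = 20,
                                 max_iter = 100, tol = 1e-6, seed = 1,
                                 label = "A") {
  widths <- widths[widths <= min(nchar(peptides))]
  if (!length(widths)) stop("discover_motif_sweep(): no feasible width", call. = FALSE)
  models <- lapply(widths, function(w) {
    discover_motif(peptides, w, n_seeds = n_seeds, max_iter = max_iter,
                   tol = tol, seed = seed, label = label)
  })
  ic <- vapply(models, function(m) mean(m$info_per_col), numeric(1))
  models[[which.max(ic)]]
}

#' Scan a peptide for motif occurrences
#'
#' Scores every window with the model's log-odds matrix (bits; X residues
#' score 0) and reports all non-overlapping windows scoring at least
#' `min_bits`, selected greedily best-score-first with ties broken by the
#' smaller offset.
#'
#' @param model a [discover_motif()] result.
#' @param peptide amino-acid string.
#' @param min_bits occurrence threshold in bits (default 8).
#' @return data.frame with columns `offset` (0-based) and `score`, ordered
#'   by offset.
#' @export
scan_motif <- function(model, peptide, min_bits = 8) {
  w <- model$width
  if (nchar(peptide) < w) {
    return(data.frame(offset = integer(0), score = numeric(0)))
  }
  wm <- .window_matrix(peptide, w)
  logmat <- cbind(model$logodds, 0)
  scores <- .score_windows(wm$W, logmat)
  cand <- order(-scores, wm$offset)
  chosen <- integer(0)
  for (i in cand) {
    if (scores[i] < min_bits) break
    o <- wm$offset[i]
    if (!length(chosen) || all(abs(o - chosen) >= w)) chosen <- c(chosen, o)
  }
  chosen <- sort(chosen)
  data.frame(offset = chosen,
             score = scores[match(chosen, wm$offset)])
}

#' Classify peptides by motif content
#'
#' Scans each peptide with every model; the assigned label is the model with
#' the highest total occurrence score (ties go to the earlier model in
#' `models`), or `"none"` when no model yields an occurrence. Occurrence
#' lists for every model are retained in the `occurrences` attribute for
#' diagnostics.
#'
#' @param ids,peptides parallel id and sequence vectors.
#' @param models named list of `motif_model`s (e.g. `list(A = ..., B = ...)`).
#' @param min_bits occurrence threshold passed to [scan_motif()].
#' @return data.frame `peptide_id`, `label`, `n_occurrences`, `offsets`
#'   (comma-joined), `total_score`; attribute `occurrences` holds the full
#'   per-model scan results.
#' @export
classify_peptides <- function(ids, peptides, models, min_bits = 8) {
  stopifnot(length(ids) == length(peptides), length(models) >= 1)
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, character(1), "label")
  }
  diag <- list()
  rows <- lapply(seq_along(ids), function(i) {
    occ <- lapply(models, scan_motif, peptide = peptides[i],
                  min_bits = min_bits)
    diag[[ids[i]]] <<- occ
    totals <- vapply(occ, function(d) sum(d$score), numeric(1))
    hit <- vapply(occ, nrow, integer(1)) > 0
    if (!any(hit)) {
      data.frame(peptide_id = ids[i], label = "none", n_occurrences = 0L,
                 offsets = "", total_score = 0, stringsAsFactors = FALSE)
    } else {
      totals[!hit] <- -Inf
      best <- which.max(totals)  # first max -> earlier model wins ties
      data.frame(peptide_id = ids[i], label = names(models)[best],
                 n_occurrences = nrow(occ[[best]]),
                 offsets = paste(occ[[best]]$offset, collapse = ","),
                 total_score = totals[best], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "occurrences") <- diag
  out
}

#' Shared consensus k-mers between two motifs
#'
#' All k-mers common to the two consensus strings, with their 0-based
#' positions in each consensus (all position combinations listed). Used to
#' surface conserved cores shared between otherwise distinct motifs, such
#' as an ALV tripeptide.
#'
#' @param model_a,model_b `motif_model`s (consensi at least `k` long).
#' @param k k-mer size (default 3).
#' @return data.frame `kmer`, `pos_a`, `pos_b`.
#' @export
shared_kmer_report <- function(model_a, model_b, k = 3) {
  ca <- model_a$consensus; cb <- model_b$consensus
  stopifnot(nchar(ca) >= k, nchar(cb) >= k)
  kmers_of <- function(s) {
    n <- nchar(s) - k + 1
    data.frame(kmer = substring(s, 1:n, k:(k + n - 1)), pos = 0:(n - 1),
               stringsAsFactors = FALSE)
  }
  ka <- kmers_of(ca); kb <- kmers_of(cb)
  shared <- merge(ka, kb, by = "kmer", suffixes = c("_a", "_b"))
  shared <- shared[order(shared$kmer, shared$pos_a, shared$pos_b), , drop = FALSE]
  rownames(shared) <- NULL
  shared
}

#' Serialise motif models in MEME minimal text format
#'
#' @param models list of `motif_model`s sharing a background.
#' @param path output file.
#' @export
write_meme_minimal <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- models[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
               "Background letter frequencies"), con)
  writeLines(paste(sprintf("%s %.5f", names(bg), bg), collapse = " "), con)
  for (m in models) {
    writeLines(c("", sprintf("MOTIF %s", m$label),
                 sprintf("letter-probability matrix: alength= 20 w= %d",
                         m$width)), con)
    for (j in seq_len(m$width)) {
      writeLines(paste(sprintf("%.6f", m$pwm[j, ]), collapse = " "), con)
    }
  }
  invisible(path)
}
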