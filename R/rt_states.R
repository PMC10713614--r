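#' @name rt_states
#' @title Gaussian-HMM segmentation of replication timing
#' @description RT profiles are segmented with a univariate Gaussian hidden
#'   Markov model fitted by Baum-Welch EM over the concatenated
#'   per-chromosome bin sequences. Chains restart from the initial state
#'   distribution at every chromosome start and after every gap of missing
#'   bins, so unmappable regions never propagate state information. With the
#'   default three states, states are ranked by their fitted mean into early
#'   (E), mid (M) and late (L); M bins are then split at RT = 0 into E-like
#'   (RT > 0, and exactly 0 by the documented tie rule) and L-like (RT < 0),
#'   yielding the four-class labeling used throughout.
NULL

# contiguous runs of defined bins, per chromosome
.defined_segments <- function(rt) {
  layout <- rt$layout
  segs <- list()
  for (ch in layout$chroms) {
    idx <- chrom_bins(layout, ch)
    def <- !is.na(rt$values[idx])
    if (!any(def)) next
    r <- rle(def)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      segs[[length(segs) + 1L]] <- idx[starts[k]:ends[k]]
  }
  segs
}

.emission_logdens <- function(y, means, vars) {
  sapply(seq_along(means), function(k)
    stats::dnorm(y, means[k], sqrt(vars[k]), log = TRUE))
}

# scaled forward-backward for one observation vector; returns loglik,
# posteriors gamma (T x K) and summed xi (K x K)
.forward_backward <- function(logb, init, trans) {
  Tn <- nrow(logb); K <- ncol(logb)
  b <- exp(logb - apply(logb, 1, max))
  bmax <- apply(logb, 1, max)
  alpha <- matrix(0, Tn, K); beta <- matrix(0, Tn, K)
  cvec <- numeric(Tn)
  a <- init * b[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% trans) * b[t, ]
    cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
  }
  beta[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1)
    beta[t, ] <- (trans %*% (b[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  if (Tn > 1) for (t in 1:(Tn - 1)) {
    m <- outer(alpha[t, ], b[t + 1, ] * beta[t + 1, ]) * trans / cvec[t + 1]
    xi <- xi + m
  }
  list(loglik = sum(log(cvec)) + sum(bmax), gamma = gamma, xi = xi)
}

#' Fit a Gaussian HMM to an RT profile
#'
#' Baum-Welch EM with deterministic initialization: state means at the
#' 25th/50th/75th RT percentiles (evenly spaced interior percentiles for
#' other state counts), variances at the global variance, transition matrix
#' with 0.9 self-transition, uniform initial distribution. The seed is only
#' consumed when `restarts > 0`, in which case additional runs start from
#' jittered means and the best log-likelihood wins.
#'
#' @param rt `BinnedTrack` of log2(E/L) values.
#' @param n_states Number of hidden states (default 3).
#' @param seed Seed for optional random restarts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param restarts Number of random restarts in addition to the
#'   deterministic initialization.
#' @return Object of class `HMMParams`: `means`, `vars`, `trans`, `init`,
#'   `loglik_trace`, `converged`, `var_floored`.
#' @export
fit_rt_hmm <- function(rt, n_states = 3L, seed = 1L, tol = 1e-6,
                       max_iter = 200L, restarts = 0L) {
  segs <- .defined_segments(rt)
  y_all <- rt$values[unlist(segs)]
  if (length(y_all) < 10 * n_states)
    stop("need at least ", 10 * n_states, " defined bins")
  probs <- seq_len(n_states) / (n_states + 1)
  base_means <- as.numeric(stats::quantile(y_all, probs))
  inits <- list(base_means)
  if (restarts > 0L) {
    set.seed(seed)
    for (r in seq_len(restarts))
      inits[[r + 1L]] <- sort(base_means +
                                stats::rnorm(n_states, 0, stats::sd(y_all) / 2))
  }
  best <- NULL
  for (m0 in inits) {
    fit <- .em_run(rt, segs, m0, n_states, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

.em_run <- function(rt, segs, means, n_states, tol, max_iter) {
  vars <- rep(stats::var(rt$values, na.rm = TRUE), n_states)
  trans <- matrix((1 - 0.9) / (n_states - 1), n_states, n_states)
  diag(trans) <- 0.9
  init <- rep(1 / n_states, n_states)
  ys <- lapply(segs, function(idx) rt$values[idx])
  trace <- numeric(0)
  var_floored <- FALSE
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll <- 0
    g_sum <- numeric(n_states); gy <- numeric(n_states)
    gyy <- numeric(n_states); xi <- matrix(0, n_states, n_states)
    init_acc <- numeric(n_states)
    gammas <- vector("list", length(ys))
    for (s in seq_along(ys)) {
      logb <- matrix(.emission_logdens(ys[[s]], means, vars),
                     ncol = n_states)
      fb <- .forward_backward(logb, init, trans)
      ll <- ll + fb$loglik
      gammas[[s]] <- fb$gamma
      g_sum <- g_sum + colSums(fb$gamma)
      gy <- gy + colSums(fb$gamma * ys[[s]])
      gyy <- gyy + colSums(fb$gamma * ys[[s]]^2)
      xi <- xi + fb$xi
      init_acc <- init_acc + fb$gamma[1, ]
    }
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - trace[it - 1]) <
          tol * (abs(trace[it - 1]) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    means <- gy / g_sum
    vars <- gyy / g_sum - means^2
    if (any(vars < 1e-8)) {
      vars <- pmax(vars, 1e-8)
      var_floored <- TRUE
    }
    rs <- rowSums(xi)
    for (k in seq_len(n_states))
      trans[k, ] <- if (rs[k] > 0) xi[k, ] / rs[k] else 1 / n_states
    init <- init_acc / sum(init_acc)
  }
  structure(list(n_states = n_states, means = means, vars = vars,
                 trans = trans, init = init, loglik_trace = trace,
                 loglik = trace[length(trace)], converged = converged,
                 var_floored = var_floored),
            class = "HMMParams")
}

#' @export
print.HMMParams <- function(x, ...) {
  cat(sprintf("HMMParams: %d states, means %s, loglik %.2f (%s)\n",
              x$n_states, paste(sprintf("%.3f", x$means), collapse = "/"),
              x$loglik, if (x$converged) "converged" else "max_iter"))
  invisible(x)
}

.viterbi <- function(y, means, vars, init, trans) {
  Tn <- length(y); K <- length(means)
  logb <- matrix(.emission_logdens(y, means, vars), ncol = K)
  logt <- log(trans)
  delta <- matrix(-Inf, Tn, K); psi <- matrix(0L, Tn, K)
  delta[1, ] <- log(init) + logb[1, ]
  if (Tn > 1) for (t in 2:Tn) for (k in seq_len(K)) {
    cand <- delta[t - 1, ] + logt[, k]
    psi[t, k] <- which.max(cand)
    delta[t, k] <- cand[psi[t, k]] + logb[t, k]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Viterbi-decode per-bin HMM states
#'
#' Deterministic maximum-probability path per contiguous run of defined
#' bins; missing bins stay undefined and break the chain (decoding restarts
#' from the initial distribution after each gap).
#'
#' @param rt `BinnedTrack` of RT values.
#' @param params Fitted `HMMParams`.
#' @return Integer vector of per-bin state ordinals (NA on missing bins).
#' @export
decode_states <- function(rt, params) {
  states <- rep(NA_integer_, rt$layout$total_bins)
  for (idx in .defined_segments(rt))
    states[idx] <- .viterbi(rt$values[idx], params$means, params$vars,
                            params$init, params$trans)
  states
}

#' Map HMM states to the four RT classes
#'
#' States are ranked by fitted mean: highest = E, lowest = L, middle = M
#' (ties broken by smaller variance, flagged). M bins are split at RT = 0:
#' `rt > 0` is E-like, `rt < 0` is L-like, and exactly 0 goes to E-like.
#'
#' @param states Integer per-bin state ordinals from [decode_states()].
#' @param rt The RT `BinnedTrack` that was decoded.
#' @param params Fitted `HMMParams` (3 states).
#' @return Object of class `RTStateSegmentation`: `state` (ordinals),
#'   `class` (character in E/E-like/L-like/L, NA undefined), `rt`, `params`.
#' @export
label_states <- function(states, rt, params) {
  if (params$n_states != 3L)
    stop("four-class labeling requires a 3-state model")
  o <- order(params$means, params$vars)   # ascending: L, M, E
  if (anyDuplicated(params$means))
    warning("tied state means; ranked by variance")
  rank_of <- integer(3); rank_of[o] <- 1:3
  cls <- rep(NA_character_, length(states))
  def <- !is.na(states)
  r <- rank_of[states[def]]
  cls_def <- character(sum(def))
  cls_def[r == 3] <- "E"
  cls_def[r == 1] <- "L"
  mid <- r == 2
  cls_def[mid] <- ifelse(rt$values[def][mid] >= 0, "E-like", "L-like")
  cls[def] <- cls_def
  structure(list(state = states, class = cls, rt = rt, params = params),
            class = "RTStateSegmentation")
}

#' @export
print.RTStateSegmentation <- function(x, ...) {
  tab <- table(factor(x$class, c("E", "E-like", "L-like", "L")))
  cat("RTStateSegmentation:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Segment an RT profile into the four RT classes
#'
#' One-call wrapper: [fit_rt_hmm()] then [decode_states()] then
#' [label_states()].
#'
#' @inheritParams fit_rt_hmm
#' @return An `RTStateSegmentation`.
#' @export
segment_rt <- function(rt, n_states = 3L, seed = 1L, tol = 1e-6,
                       max_iter = 200L, restarts = 0L) {
  params <- fit_rt_hmm(rt, n_states, seed, tol, max_iter, restarts)
  label_states(decode_states(rt, params), rt, params)
}

#' Mode of a kernel density estimate
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth evaluated on a
#' regular grid; the mode is the grid argmax. If a second local maximum
#' comes within 1% of the peak density, an `ambiguous` attribute is set.
#'
#' @param x Numeric values.
#' @param grid_points Grid size.
#' @param from,to Optional grid limits (default data range).
#' @return Scalar mode with attribute `ambiguous`.
#' @export
kde_mode <- function(x, grid_points = 512, from = min(x), to = max(x)) {
  x <- x[is.finite(x)]
  d <- stats::density(x, bw = "nrd0", n = grid_points, from = from, to = to)
  i <- which.max(d$y)
  loc_max <- which(diff(sign(diff(d$y))) == -2) + 1L
  amb <- sum(d$y[loc_max] >= 0.99 * d$y[i]) > 1
  structure(d$x[i], ambiguous = amb)
}

#' Cross-condition RT distributions per reference RT class
#'
#' For each of the four reference classes, collects the RT values of those
#' same bins in every condition and summarizes each distribution (n, mean,
#' median, KDE mode), mirroring the per-state RT shift analysis of a
#' reference condition against perturbations.
#'
#' @param seg Reference `RTStateSegmentation`.
#' @param rt_by_condition Named list of RT `BinnedTrack`s on the same
#'   layout.
#' @return List with `values` (nested `class -> condition -> numeric`) and
#'   `summary` (data.frame of class, condition, n, mean, median, mode).
#' @export
state_shift_summary <- function(seg, rt_by_condition) {
  stopifnot(length(rt_by_condition) >= 1, !is.null(names(rt_by_condition)))
  for (t in rt_by_condition)
    stop_if_layout_mismatch(seg$rt$layout, t$layout)
  classes <- c("E", "E-like", "L-like", "L")
  values <- list()
  rows <- list()
  for (cl in classes) {
    bins <- which(!is.na(seg$class) & seg$class == cl)
    if (length(bins) == 0L) warning("empty RT class: ", cl)
    values[[cl]] <- list()
    for (cond in names(rt_by_condition)) {
      v <- rt_by_condition[[cond]]$values[bins]
      v <- v[!is.na(v)]
      values[[cl]][[cond]] <- v
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, condition = cond, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        median = if (length(v)) stats::median(v) else NA_real_,
        mode = if (length(v) >= 2) as.numeric(kde_mode(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(values = values, summary = do.call(rbind, rows))
}

#' Export an RT-state segmentation as BED segments
#'
#' Merges runs of equal class labels into intervals (name = class).
#'
#' @param seg An `RTStateSegmentation`.
#' @return A `GRanges` with a `name` column.
#' @export
segmentation_to_intervals <- function(seg) {
  layout <- seg$rt$layout
  ch <- bin_chroms(layout); st <- bin_starts(layout); en <- bin_ends(layout)
  cls <- ifelse(is.na(seg$class), "undefined", seg$class)
  key <- paste(ch, cls)
  r <- rle(key)
  ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1L
  keep <- cls[starts_i] != "undefined"
  gr <- GenomicRanges::GRanges(
    seqnames = ch[starts_i[keep]],
    ranges = IRanges::IRanges(start = st[starts_i[keep]] + 1L,
                              end = en[ends_i[keep]]),
    name = cls[starts_i[keep]])
  GenomeInfoDb::seqlengths(gr) <- layout$lengths[GenomeInfoDb::seqlevels(gr)]
  gr
}
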