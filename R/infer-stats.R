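#' Welch's t test on two samples of isotopologue fractions
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom,
#' `t = (mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)`; optionally paired
#' (then an ordinary paired t test on the differences) or one-tailed.
#'
#' @param x,y Numeric samples (each of length >= 2; equal lengths when
#'   paired).
#' @param tails 1 or 2. One-tailed tests report the tail of the observed
#'   direction of `mean(x) - mean(y)`.
#' @param paired Logical.
#' @return List of class `ppp_comparison`: `mean_x`, `mean_y`, `t`, `df`,
#'   `p`, `tails`, `paired`.
#' @export
welch_t <- function(x, y, tails = 2L, paired = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least two observations", call. = FALSE)
  if (!tails %in% c(1L, 2L)) stop("tails must be 1 or 2", call. = FALSE)
  if (paired && length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both samples have zero variance: the t statistic is undefined",
         call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = FALSE, paired = paired)
  p <- ht$p.value
  if (tails == 1L) p <- p / 2
  structure(list(mean_x = mean(x), mean_y = mean(y),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = p, tails = as.integer(tails), paired = paired),
            class = "ppp_comparison")
}

#' @export
print.ppp_comparison <- function(x, ...) {
  cat(sprintf("%s%s t = %.4g, df = %.3f, p = %.4g (%d-tailed)\n",
              if (x$paired) "paired " else "Welch ",
              "t test:", x$t, x$df, x$p, x$tails))
  invisible(x)
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Raw p values are sorted ascending; the i-th smallest is adjusted to
#' `1 - (1 - p_(i))^(m - i + 1)`, a running maximum enforces monotonicity,
#' and results are mapped back to input order.
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @param alpha Family-wise error rate for the reject flags.
#' @return Data frame with `p`, `p_adjusted`, `reject`.
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  data.frame(p = p, p_adjusted = out, reject = out <= alpha)
}

#' Group comparison of isotopologue fractions across a fraction table
#'
#' Runs Welch's t test per (metabolite, mass shift) between two groups and
#' applies the Holm-Sidak adjustment within each family. The default family
#' is one metabolite (all its mass shifts), mirroring per-panel adjustment
#' of published MID plots; `family = "global"` pools every test.
#'
#' @param fractions Long data frame from [fraction_table()] (columns
#'   `sample_id`, `group`, `metabolite`, `mass_shift`, `fraction`).
#' @param group_x,group_y Group labels to compare (x vs y).
#' @param tails 1 or 2.
#' @param alpha Family-wise error rate.
#' @param family `"metabolite"` or `"global"`.
#' @return Data frame with one row per (metabolite, mass shift): group
#'   means, `t`, `df`, `p`, `p_adjusted`, `reject`.
#' @export
compare_groups <- function(fractions, group_x, group_y, tails = 2L,
                           alpha = 0.05,
                           family = c("metabolite", "global")) {
  family <- match.arg(family)
  fx <- fractions[fractions$group == group_x, ]
  fy <- fractions[fractions$group == group_y, ]
  if (!nrow(fx) || !nrow(fy))
    stop("both groups must be present in the fraction table", call. = FALSE)
  keys <- unique(fractions[, c("metabolite", "mass_shift")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    mb <- keys$metabolite[i]; ms <- keys$mass_shift[i]
    x <- fx$fraction[fx$metabolite == mb & fx$mass_shift == ms]
    y <- fy$fraction[fy$metabolite == mb & fy$mass_shift == ms]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    res <- tryCatch(welch_t(x, y, tails = tails),
                    error = function(e) NULL)
    if (is.null(res)) {
      # degenerate (constant) fractions: no test possible
      data.frame(metabolite = mb, mass_shift = ms, mean_x = mean(x),
                 mean_y = mean(y), t = NA_real_, df = NA_real_,
                 p = NA_real_)
    } else {
      data.frame(metabolite = mb, mass_shift = ms, mean_x = res$mean_x,
                 mean_y = res$mean_y, t = res$t, df = res$df, p = res$p)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_; out$reject <- NA
  fam <- if (family == "metabolite") out$metabolite else "all"
  for (f in unique(fam)) {
    idx <- which(fam == f & !is.na(out$p))
    if (length(idx)) {
      hs <- holm_sidak(out$p[idx], alpha)
      out$p_adjusted[idx] <- hs$p_adjusted
      out$reject[idx] <- hs$reject
    }
  }
  rownames(out) <- NULL
  out
}

#' Oxidative vs nonoxidative PPP marker scores
#'
#' Sums the diagnostic isotopologue fractions: m+3 and m+5 of the combined
#' ribulose-5P/ribose-5P pool and m+5 of sedoheptulose-7P mark the
#' oxidative/cyclic branch; m+2 ribulose-5P/ribose-5P and m+4
#' sedoheptulose-7P mark the nonoxidative branch.
#'
#' @param mids Named list of MIDs containing `Ru5P_R5P` and `S7P`.
#' @return List of class `ppp_markers`: `oxidative`, `nonoxidative`.
#' @export
marker_scores <- function(mids) {
  pent <- mids[["Ru5P_R5P"]]; s7p <- mids[["S7P"]]
  if (is.null(pent) || is.null(s7p))
    stop("marker scores need MIDs for Ru5P_R5P and S7P", call. = FALSE)
  pick <- function(v, k) if (length(v) > k) unname(v[k + 1L]) else 0
  structure(list(
    oxidative = pick(pent, 3) + pick(pent, 5) + pick(s7p, 5),
    nonoxidative = pick(pent, 2) + pick(s7p, 4)), class = "ppp_markers")
}

#' @export
print.ppp_markers <- function(x, ...) {
  cat(sprintf("PPP marker scores: oxidative %.4f, nonoxidative %.4f\n",
              x$oxidative, x$nonoxidative))
  invisible(x)
}
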