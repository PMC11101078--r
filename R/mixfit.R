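# Nonnegative least squares. For the small systems of the mixture fit
# (a handful of regimes) the global optimum is found exactly by active-set
# enumeration: at the NNLS optimum the positive weights solve the normal
# equations restricted to their support, so scanning all supports and
# keeping the best feasible restricted solution is exact and immune to the
# cycling that iterative solvers can hit on zero-residual systems. Larger
# systems fall back to Lawson-Hanson.
nnls_solve <- function(A, y) {
  k <- ncol(A)
  if (k > 10L) return(pracma::lsqnonneg(A, y)$x)
  best <- NULL; best_rss <- Inf
  for (code in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(bitwShiftR(code, seq_len(k) - 1L), 1L) == 1L)
    xs <- tryCatch(qr.solve(A[, S, drop = FALSE], y),
                   error = function(e) NULL)
    if (is.null(xs) || any(xs < -1e-12)) next
    rss <- sum((A[, S, drop = FALSE] %*% xs - y)^2)
    if (rss < best_rss - 1e-15) {
      best_rss <- rss
      best <- numeric(k); best[S] <- pmax(xs, 0)
    }
  }
  if (is.null(best)) numeric(k) else best
}

#' Fit pathway contributions to observed isotopologue distributions
#'
#' The package's central estimator. Observed (natural-abundance-corrected)
#' MIDs are modeled as a convex combination of simulated regime templates:
#' stacking the per-metabolite fractions into a vector `y` and the
#' templates into a matrix `T`, the fit minimizes `||T w - y||^2` subject
#' to `w >= 0`, with the sum-to-one constraint imposed through an augmented
#' row of large weight followed by exact renormalization. The weights
#' estimate the share of each labeling regime (direct glycolysis, single
#' oxidative PPP pass, cyclic PPP, nonoxidative PPP) in the observed
#' labeling.
#'
#' @param observed Named list of MIDs (metabolite -> numeric vector), or a
#'   single stacked numeric vector matching `rownames(templates$matrix)`.
#' @param templates A [template_mids()] object (or a bare matrix with one
#'   column per regime).
#' @param sum_weight Weight of the augmented sum-to-one row.
#' @return Object of class `ppp_mixfit` with components `weights`
#'   (named, nonnegative, summing to 1), `residual` (Euclidean norm of
#'   `T w - y` after renormalization), `fitted`, `observed` (stacked),
#'   `templates`, `collinear` (TRUE if two templates are numerically
#'   indistinguishable). Supports `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict` and `plot`.
#' @examples
#' net <- default_network()
#' tpl <- template_mids(net, enrichment = 0.6)
#' y <- drop(tpl$matrix %*% c(0.5, 0.2, 0.2, 0.1))
#' fit <- fit_pathway_mixture(y, tpl)
#' coef(fit)
#' @export
fit_pathway_mixture <- function(observed, templates, sum_weight = 1e3) {
  A <- if (inherits(templates, "ppp_templates")) templates$matrix
       else as.matrix(templates)
  if (ncol(A) < 2L)
    stop("mixture fitting needs at least two regime templates",
         call. = FALSE)
  if (is.list(observed)) {
    y <- unlist(observed)
    if (!is.null(rownames(A))) {
      if (!setequal(names(y), rownames(A)))
        stop("observed MIDs do not cover the template metabolites",
             call. = FALSE)
      y <- y[rownames(A)]
    }
  } else {
    y <- as.numeric(observed)
    if (length(y) != nrow(A))
      stop("stacked observed vector does not match template rows",
           call. = FALSE)
  }
  collinear <- FALSE
  for (i in seq_len(ncol(A) - 1L)) for (j in (i + 1L):ncol(A))
    if (max(abs(A[, i] - A[, j])) < 1e-10) collinear <- TRUE
  if (collinear)
    warning("degenerate templates: two regimes are indistinguishable; ",
            "weights between them are arbitrary", call. = FALSE)
  A_aug <- rbind(A, rep(sum_weight, ncol(A)))
  y_aug <- c(y, sum_weight)
  w <- nnls_solve(A_aug, y_aug)
  if (sum(w) <= 0)
    stop("mixture fit degenerate: all weights zero", call. = FALSE)
  w <- w / sum(w)
  names(w) <- colnames(A)
  fitted_y <- drop(A %*% w)
  structure(list(weights = w,
                 residual = sqrt(sum((fitted_y - y)^2)),
                 fitted = fitted_y, observed = y,
                 templates = templates, collinear = collinear),
            class = "ppp_mixfit")
}

#' @export
print.ppp_mixfit <- function(x, digits = 4, ...) {
  cat("Pathway-mixture fit (nonnegative least squares on the simplex)\n")
  print(round(x$weights, digits))
  cat("residual norm:", format(x$residual, digits = 3), "\n")
  if (x$collinear) cat("warning: collinear templates\n")
  invisible(x)
}

#' @export
coef.ppp_mixfit <- function(object, ...) object$weights

#' @export
fitted.ppp_mixfit <- function(object, ...) object$fitted

#' @export
residuals.ppp_mixfit <- function(object, ...)
  object$observed - object$fitted

#' Predicted MIDs under fitted (or supplied) mixture weights
#'
#' @param object A `ppp_mixfit`.
#' @param weights Optional replacement weights (named like the fit's).
#' @param ... Unused.
#' @return Named list of per-metabolite MIDs implied by the weights, when
#'   the fit was made against a `ppp_templates`; otherwise the stacked
#'   fitted vector.
#' @export
predict.ppp_mixfit <- function(object, weights = NULL, ...) {
  tpl <- object$templates
  w <- if (is.null(weights)) object$weights else weights[names(object$weights)]
  A <- if (inherits(tpl, "ppp_templates")) tpl$matrix else as.matrix(tpl)
  yhat <- drop(A %*% w)
  if (!inherits(tpl, "ppp_templates")) return(yhat)
  out <- lapply(tpl$metabolites, function(mb) {
    idx <- grep(paste0("^", mb, "\\.m"), rownames(A))
    v <- yhat[idx]
    names(v) <- sub(paste0(mb, "."), "", rownames(A)[idx], fixed = TRUE)
    v
  })
  stats::setNames(out, tpl$metabolites)
}

#' @export
summary.ppp_mixfit <- function(object, ...) {
  res <- residuals(object)
  per_met <- NULL
  if (inherits(object$templates, "ppp_templates")) {
    mets <- object$templates$metabolites
    per_met <- vapply(mets, function(mb) {
      idx <- grep(paste0("^", mb, "\\.m"), names(res))
      sqrt(sum(res[idx]^2))
    }, 1)
  }
  structure(list(weights = object$weights, residual = object$residual,
                 per_metabolite_residual = per_met,
                 collinear = object$collinear),
            class = "summary.ppp_mixfit")
}

#' @export
print.summary.ppp_mixfit <- function(x, ...) {
  cat("Pathway-mixture fit\n\nRegime weights:\n")
  print(round(x$weights, 4))
  cat("\nTotal residual norm:", format(x$residual, digits = 3), "\n")
  if (!is.null(x$per_metabolite_residual)) {
    cat("Per-metabolite residual norms:\n")
    print(round(x$per_metabolite_residual, 4))
  }
  if (x$collinear) cat("\nwarning: collinear templates\n")
  invisible(x)
}

#' @export
plot.ppp_mixfit <- function(x, ...) {
  obs <- x$observed; fit <- x$fitted
  op <- graphics::par(mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rbind(obs, fit), beside = TRUE,
                    names.arg = names(obs), las = 2, cex.names = 0.6,
                    col = c("grey30", "steelblue"),
                    ylab = "fraction",
                    main = "Observed vs fitted isotopologue fractions", ...)
  graphics::legend("topright", c("observed", "fitted"),
                   fill = c("grey30", "steelblue"), bty = "n")
  invisible(x)
}
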