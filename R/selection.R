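#' Prune collinear predictors by correlation and single-variable AIC
#'
#' While any retained pair of layers has |Pearson r| above `threshold`
#' (correlations computed over cells where all stack layers are valid),
#' the worst-offending pair is resolved by fitting two single-predictor
#' binomial GAMs on the design and removing the predictor whose model has
#' the higher AIC.  AIC ties within `1e-6` are broken by keeping the
#' lexicographically smaller name (logged in the report).
#'
#' @param stack a `predictor_stack` (>= 2 layers).
#' @param design design table from [make_design()] with both labels and a
#'   column per stack layer.
#' @param threshold absolute correlation cutoff (default 0.7).
#' @param k basis dimension for the single-variable GAMs (default 5).
#' @return list of class `selection_report`: `retained` (names), `removed`
#'   (data.frame: name, partner, r, aic_removed, aic_kept, tie_break),
#'   `correlation` (final retained-set correlation matrix).
#' @export
prune_collinear <- function(stack, design, threshold = 0.7, k = 5L) {
  if (length(stack) < 2L) stop("need at least two predictors")
  all_ok <- Reduce(`&`, lapply(stack, function(g) is.finite(g$values)))
  retained <- names(stack)
  removed <- data.frame(name = character(), partner = character(),
                        r = numeric(), aic_removed = numeric(),
                        aic_kept = numeric(), tie_break = logical())
  aic1 <- function(nm) {
    sp <- build_smooth(design[[nm]], k = k, predictor = nm)
    fit_gam(design, list(sp))$aic
  }
  repeat {
    if (length(retained) < 2L) break
    r <- pairwise_correlation(stack[retained], at_cells = all_ok)
    ra <- abs(r); diag(ra) <- 0
    if (all(is.na(ra)) || max(ra, na.rm = TRUE) <= threshold) break
    ij <- which(ra == max(ra, na.rm = TRUE), arr.ind = TRUE)
    pair <- sort(c(rownames(ra)[ij[1L, 1L]], colnames(ra)[ij[1L, 2L]]))
    a1 <- aic1(pair[1L]); a2 <- aic1(pair[2L])
    tie <- abs(a1 - a2) <= 1e-6
    drop_nm <- if (tie) pair[2L] else pair[which.max(c(a1, a2))]
    keep_nm <- setdiff(pair, drop_nm)
    removed <- rbind(removed, data.frame(
      name = drop_nm, partner = keep_nm,
      r = r[pair[1L], pair[2L]],
      aic_removed = if (drop_nm == pair[1L]) a1 else a2,
      aic_kept = if (keep_nm == pair[1L]) a1 else a2,
      tie_break = tie))
    retained <- setdiff(retained, drop_nm)
  }
  final_r <- if (length(retained) >= 2L)
    pairwise_correlation(stack[retained], at_cells = all_ok) else NULL
  structure(list(retained = retained, removed = removed,
                 correlation = final_r, threshold = threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("predictor selection (|r| > %.2f):\n", x$threshold))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$removed) == 0L) cat("  removed : none\n") else
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("  removed : %s (r = %.3f with %s; AIC %.2f vs %.2f%s)\n",
                  x$removed$name[i], x$removed$r[i], x$removed$partner[i],
                  x$removed$aic_removed[i], x$removed$aic_kept[i],
                  if (x$removed$tie_break[i]) "; lexicographic tie-break" else ""))
  invisible(x)
}

#' Serialize a selection report to JSON
#'
#' @param report a `selection_report`.
#' @param path output path.
#' @export
write_selection_report <- function(report, path) {
  jsonlite::write_json(list(retained = report$retained,
                            removed = report$removed,
                            threshold = report$threshold),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Concurvity index of each fitted smooth term
#'
#' For each smooth, the proportion of its fitted contribution (the term's
#' basis columns times its coefficients, over the training rows) that lies
#' in the column span of the intercept and all other terms' bases: the
#' squared norm of the projection divided by the squared norm.  0 means the
#' term is orthogonal to the rest of the model; 1 means it is entirely
#' reproducible from the other terms (the nonlinear analogue of perfect
#' collinearity).
#'
#' @param fit a `gam_fit` with at least one smooth term.
#' @param threshold advisory flag cutoff (default 0.8).
#' @return named numeric vector in [0, 1], with a logical `"flagged"`
#'   attribute marking terms above `threshold`.
#' @export
concurvity_index <- function(fit, threshold = 0.8) {
  nterm <- length(fit$specs)
  if (nterm == 0L) stop("fit has no smooth terms")
  out <- stats::setNames(numeric(nterm), fit$predictors)
  for (j in seq_len(nterm)) {
    g <- fit$X[, fit$idx[[j]], drop = FALSE] %*% fit$coefficients[[j]]
    denom <- sum(g^2)
    if (denom < 1e-12 || nterm == 1L) { out[j] <- 0; next }
    others <- fit$X[, -fit$idx[[j]], drop = FALSE]  # intercept + other terms
    qrm <- qr(others)
    proj <- qr.fitted(qrm, g)
    out[j] <- min(1, max(0, sum(proj^2) / denom))
  }
  attr(out, "flagged") <- out > threshold
  out
}
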