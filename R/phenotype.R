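#' Aggregate repeated phenotype records to one row per ewe
#'
#' When the phenotype table holds one row per ewe-year, fecundity is averaged
#' across years and the covariates are taken from the most recent record.
#' Tables already holding one row per ewe pass through unchanged.
#'
#' @param phenotypes phenotype data frame (`id`, `year`, covariates,
#'   `fecundity`).
#' @return data frame with one row per ewe.
#' @export
aggregate_phenotypes <- function(phenotypes) {
  if (!anyDuplicated(phenotypes$id)) return(phenotypes)
  parts <- split(phenotypes, phenotypes$id)
  out <- do.call(rbind, lapply(parts, function(d) {
    latest <- d[which.max(d$year), , drop = FALSE]
    latest$fecundity <- mean(d$fecundity)
    latest
  }))
  rownames(out) <- NULL
  out[match(unique(phenotypes$id), out$id), , drop = FALSE]
}

# clamp-and-round a continuous fecundity value to the nearest of {0, 1, 2}
.round_fecundity <- function(y) pmin(2, pmax(0, round(y)))

#' Screen phenotype covariates by Wald chi-squared tests
#'
#' Fits a Gaussian identity-link linear model of fecundity on all candidate
#' covariates by least squares and tests each coefficient with a Wald
#' chi-squared statistic, `(estimate / se)^2` on 1 degree of freedom.
#' Covariates with p < `alpha` are retained for the final adjustment model.
#' Inestimable (constant or aliased) covariates are dropped with a warning.
#'
#' @param phenotypes phenotype data frame, one row per ewe (see
#'   [aggregate_phenotypes()]).
#' @param covariates covariate column names to screen.
#' @param alpha retention threshold on the Wald p-value (default 0.05).
#' @return object of class `covariate_screen`: coefficient table with Wald
#'   statistics and p-values, retained covariate names, dropped covariates.
#' @export
screen_covariates <- function(phenotypes,
                              covariates = c("year", "age", "body_condition",
                                             "hours_estrus", "n_births"),
                              alpha = 0.05) {
  covariates <- intersect(covariates, names(phenotypes))
  dropped <- character(0)
  for (v in covariates) {
    if (length(unique(phenotypes[[v]])) < 2) {
      .warnf("covariate '%s' is constant and was excluded from screening", v)
      dropped <- c(dropped, v)
    }
  }
  covariates <- setdiff(covariates, dropped)
  if (length(covariates) == 0) .stopf("no non-constant covariates to screen")

  fml <- stats::as.formula(paste("fecundity ~", paste(covariates, collapse = " + ")))
  fit <- stats::lm(fml, data = phenotypes)
  cf <- summary(fit)$coefficients
  aliased <- setdiff(c("(Intercept)", covariates), rownames(cf))
  if (length(aliased)) {
    .warnf("aliased (collinear) covariate(s) dropped: %s",
           paste(aliased, collapse = ", "))
    dropped <- c(dropped, aliased)
  }
  wald <- (cf[, "Estimate"] / cf[, "Std. Error"])^2
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  tab <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                    se = cf[, "Std. Error"], wald = wald, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  retained <- setdiff(tab$term[tab$p < alpha], "(Intercept)")
  structure(list(coefficients = tab, retained = retained, dropped = dropped,
                 alpha = alpha, model = fit),
            class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat("Wald chi-squared covariate screen (alpha =", x$alpha, ")\n")
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  cat("retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Fit the final fecundity adjustment model
#'
#' Least-squares fit of `fecundity = beta0 + beta1 * body_condition`. The
#' fitted values are the adjusted phenotypes used by all downstream stages.
#' Prediction accuracy is the fraction of ewes whose fitted value, rounded
#' to the nearest of {0, 1, 2}, equals the (equally rounded) observed
#' outcome.
#'
#' @param phenotypes phenotype data frame, one row per ewe, with columns
#'   `body_condition` and `fecundity` (>= 3 rows).
#' @return object of class `fecundity_fit` with `beta0`, `beta1`, `fitted`
#'   (named by ewe id), `accuracy`, the coefficient table and the underlying
#'   `lm` fit.
#' @export
fit_final_model <- function(phenotypes) {
  if (nrow(phenotypes) < 3) .stopf("need at least 3 ewes to fit the model")
  constant_bc <- length(unique(phenotypes$body_condition)) < 2
  if (constant_bc) {
    .warnf("body condition is constant; fitting intercept-only model")
    fit <- stats::lm(fecundity ~ 1, data = phenotypes)
    beta1 <- 0
  } else {
    fit <- stats::lm(fecundity ~ body_condition, data = phenotypes)
    beta1 <- unname(stats::coef(fit)["body_condition"])
  }
  beta0 <- unname(stats::coef(fit)["(Intercept)"])
  fitted <- stats::setNames(stats::fitted(fit), phenotypes$id)
  accuracy <- mean(.round_fecundity(fitted) ==
                     .round_fecundity(phenotypes$fecundity))
  structure(list(beta0 = beta0, beta1 = beta1, fitted = fitted,
                 accuracy = accuracy, model = fit,
                 intercept_only = constant_bc),
            class = "fecundity_fit")
}

#' @export
print.fecundity_fit <- function(x, ...) {
  cat(sprintf("Fecundity adjustment model: y = %.4f + %.4f * body_condition\n",
              x$beta0, x$beta1))
  cat(sprintf("  prediction accuracy (rounded to 0/1/2): %.1f%%\n",
              100 * x$accuracy))
  invisible(x)
}

#' @export
coef.fecundity_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' @export
predict.fecundity_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  stats::predict(object$model, newdata = newdata)
}

#' @export
residuals.fecundity_fit <- function(object, ...) stats::residuals(object$model)

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. Written out explicitly (rather than delegating to
#' `t.test`) so the base implementation can serve as an independent check;
#' the degenerate case of two identical constant groups returns t = 0,
#' p = 1.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) .stopf("need at least 2 values per group")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  se2 <- va + vb
  d <- mean(a) - mean(b)
  if (se2 == 0) {
    if (d == 0) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(d) * Inf, df = length(a) + length(b) - 2, p = 0))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Assign ewes to high/low fecundity groups by hierarchical clustering
#'
#' Agglomerative hierarchical clustering (complete linkage by default) on
#' the Euclidean distance matrix of adjusted phenotypes, cut at k = 2. The
#' group with the larger mean adjusted phenotype is labelled `"high"`. The
#' group difference is tested with Welch's unequal-variance t-test and the
#' dendrogram is exported as Newick text.
#'
#' @param adjusted named numeric vector of adjusted phenotypes (fitted
#'   values), names = ewe ids.
#' @param k number of groups to cut (default 2).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return object of class `group_assignment`: `assignments` data frame
#'   (`id`, `label`, `adjusted`), per-group means and standard errors, the
#'   Welch test (`t`, `df`, `p`), the `hclust` tree and its Newick export.
#' @export
assign_groups <- function(adjusted, k = 2, linkage = "complete") {
  if (length(adjusted) < 2) .stopf("need at least 2 ewes")
  if (length(unique(adjusted)) < 2)
    .stopf("all adjusted phenotypes are identical; no group structure to find")
  ids <- names(adjusted)
  if (is.null(ids)) ids <- sprintf("IND%04d", seq_along(adjusted))

  hc <- stats::hclust(stats::dist(adjusted), method = linkage)
  cl <- stats::cutree(hc, k = k)
  means_by_cl <- tapply(adjusted, cl, mean)
  # orient: largest-mean cluster is "high"; with k > 2 remaining clusters
  # are labelled low2, low3, ... in decreasing mean order
  ord <- order(means_by_cl, decreasing = TRUE)
  labs <- c("high", "low", if (k > 2) paste0("low", seq_len(k - 2) + 1))
  label <- labs[match(cl, as.integer(names(means_by_cl))[ord])]

  assignments <- data.frame(id = ids, label = label, adjusted = unname(adjusted),
                            stringsAsFactors = FALSE)
  gmeans <- tapply(assignments$adjusted, assignments$label, mean)
  gse <- tapply(assignments$adjusted, assignments$label,
                function(v) stats::sd(v) / sqrt(length(v)))
  welch <- NULL
  if (k == 2) {
    a <- assignments$adjusted[label == "high"]
    b <- assignments$adjusted[label == "low"]
    if (length(a) >= 2 && length(b) >= 2) {
      welch <- welch_t_test(a, b)
    } else {
      .warnf("a fecundity group has fewer than 2 ewes; Welch test not computed")
    }
  }

  phylo <- ape::as.phylo(hc)
  newick <- ape::write.tree(phylo)

  structure(list(assignments = assignments, means = gmeans, se = gse,
                 welch = welch, hclust = hc, newick = newick,
                 linkage = linkage, k = k),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  tab <- table(x$assignments$label)
  cat("Fecundity groups (hierarchical clustering,", x$linkage, "linkage):\n")
  for (g in names(x$means))
    cat(sprintf("  %-5s n = %2d, mean adjusted = %.4f (se %.4f)\n",
                g, tab[g], x$means[g], x$se[g]))
  if (!is.null(x$welch))
    cat(sprintf("  Welch t = %.3f, df = %.1f, p = %.3g\n",
                x$welch$t, x$welch$df, x$welch$p))
  invisible(x)
}

#' @export
plot.group_assignment <- function(x, ...) {
  graphics::plot(x$hclust, labels = x$assignments$id,
                 main = "Adjusted-phenotype dendrogram", xlab = "", sub = "", ...)
  invisible(x)
}
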