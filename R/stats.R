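.pStars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Two-step inference: one-way ANOVA per feature, Tukey HSD post hoc
#'
#' For every feature, a classical one-way ANOVA over the groups of the label
#' column; wherever the ANOVA null is rejected at `alpha`, Tukey's
#' honest-significant-difference test is run over all group pairs, with
#' family-wise adjusted p-values. Cells are treated as independent
#' observations; aggregate per animal first (the `animal_id` annotation is
#' preserved for that purpose) if a nested analysis is wanted. Features with
#' zero variance in every group yield an undefined F, reported as `NA`.
#'
#' @param table a [FeatureTable-class].
#' @param grouping label column name (>= 2 groups with >= 2 cells each).
#' @param alpha ANOVA rejection level gating the post hoc tests (default 0.05).
#' @return An [AnovaTukeyResult-class]; significance stars mark p < 0.05 (*),
#'   < 0.01 (**), < 0.001 (***).
#' @export
anovaTukey <- function(table, grouping, alpha = 0.05) {
  y <- factor(groupLabels(table, grouping))
  if (nlevels(y) < 2L)
    .amStop("InsufficientSampleError", "need at least 2 groups")
  if (any(table(y) < 2L))
    .amStop("InsufficientSampleError", "every group needs at least 2 cells")
  x <- featureMatrix(table)
  an <- data.frame(feature = colnames(x), F = NA_real_, p = NA_real_,
                   stars = "", stringsAsFactors = FALSE)
  tk <- list()
  for (k in seq_len(ncol(x))) {
    v <- x[, k]
    if (var(v) == 0) {          # zero variance everywhere: F is 0/0
      an$F[k] <- NA_real_
      an$p[k] <- NA_real_
      next
    }
    fit <- aov(v ~ y)
    s <- summary(fit)[[1]]
    Fk <- s[["F value"]][1]
    pk <- s[["Pr(>F)"]][1]
    if (!is.finite(Fk)) { Fk <- NA_real_; pk <- NA_real_ }
    an$F[k] <- Fk
    an$p[k] <- pk
    if (!is.na(pk) && pk < alpha) {
      th <- TukeyHSD(fit)$y
      tk[[length(tk) + 1L]] <- data.frame(
        feature = colnames(x)[k], comparison = rownames(th),
        diff = th[, "diff"], p_adj = th[, "p adj"],
        stars = .pStars(th[, "p adj"]), row.names = NULL,
        stringsAsFactors = FALSE)
    }
  }
  an$stars <- .pStars(an$p)
  tukey <- if (length(tk)) do.call(rbind, tk) else
    data.frame(feature = character(), comparison = character(),
               diff = numeric(), p_adj = numeric(), stars = character(),
               stringsAsFactors = FALSE)
  new("AnovaTukeyResult", anova = an, tukey = tukey, alpha = alpha)
}

#' @describeIn anovaTukey per-feature ANOVA table.
#' @param x an `AnovaTukeyResult`.
#' @export
anovaTable <- function(x) x@anova

#' @describeIn anovaTukey pairwise Tukey table (features that rejected only).
#' @export
tukeyTable <- function(x) x@tukey

setMethod("show", "AnovaTukeyResult", function(object) {
  cat(sprintf("AnovaTukeyResult: %d features, alpha = %g\n",
              nrow(object@anova), object@alpha))
  cat(sprintf("  %d feature(s) rejected; %d pairwise Tukey rows\n",
              sum(object@anova$p < object@alpha, na.rm = TRUE),
              nrow(object@tukey)))
})

#' Write the ANOVA + Tukey result as a long-format CSV
#'
#' One row per feature for the ANOVA stage (`comparison = "(anova)"`) followed
#' by one row per feature x group pair for the post hoc stage.
#'
#' @param x an [AnovaTukeyResult-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeAnovaTukey <- function(x, path) {
  a <- x@anova
  long <- rbind(
    data.frame(feature = a$feature, comparison = "(anova)", statistic = a$F,
               p = a$p, stars = a$stars, stringsAsFactors = FALSE),
    if (nrow(x@tukey))
      data.frame(feature = x@tukey$feature, comparison = x@tukey$comparison,
                 statistic = x@tukey$diff, p = x@tukey$p_adj,
                 stars = x@tukey$stars, stringsAsFactors = FALSE)
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
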