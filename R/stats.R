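# Routine group statistics: t tests, one/two-factor ANOVA (optionally with a
# repeated factor), Pearson correlation, Holm- or Sidak-adjusted post-hoc
# contrasts gated on the design's gating effect, and optional Grubbs
# outlier screening.

# Two-way ANOVA with interaction from sums of squares; F defined as 0 when
# an effect's SS is exactly 0 (aov would return 0/0 = NaN on degenerate
# all-constant data).
two_way_anova_table <- function(y, f1, f2) {
  fit <- stats::aov(y ~ f1 * f2)
  # a perfect fit (all-constant cells) is a designed degenerate path; its
  # F values are redefined below, so the unreliable-F warning is moot
  an <- suppressWarnings(stats::anova(fit))
  ss <- an[["Sum Sq"]]
  df <- an[["Df"]]
  ms <- ss / df
  ms_res <- ms[4]
  eff <- c("f1", "f2", "f1:f2")
  F <- vapply(1:3, function(i) {
    if (ss[i] <= 1e-12) 0
    else if (ms_res <= 1e-12) Inf
    else ms[i] / ms_res
  }, 1)
  p <- vapply(1:3, function(i) {
    if (ss[i] <= 1e-12) 1
    else if (ms_res <= 1e-12) 0
    else stats::pf(ms[i] / ms_res, df[i], df[4], lower.tail = FALSE)
  }, 1)
  data.frame(effect = c("region", "group", "region:group"),
             df = df[1:3], df_res = df[4], F = F, p = p)
}

#' Group comparison with gated post-hoc contrasts
#'
#' One entry point for the routine inferential designs used around the
#' pipeline's outputs: unpaired and paired two-tailed t tests, Pearson
#' correlation, one-way ANOVA, two-way ANOVA with interaction, and the
#' balanced two-way design with one repeated (within-subject) factor.
#' Post-hoc pairwise contrasts (Welch t tests between levels of the first
#' factor, or of the second factor within levels of the first for two-way
#' designs) are computed only when the gating effect — the main effect for
#' one-way designs, the interaction for two-way designs — is significant at
#' `alpha`, and are multiplicity-adjusted (Holm by default).
#'
#' @param data data.frame with a numeric `value` column plus the factor
#'   columns the design needs: `group` (all designs), `factor2` (two-way
#'   designs), `subject` (paired/repeated designs), `value2` (pearson).
#' @param design one of `"t"`, `"paired_t"`, `"pearson"`, `"one_way"`,
#'   `"two_way"`, `"two_way_rm"` (repeated on `factor2`).
#' @param alpha gating level (default 0.05).
#' @param p_adjust `"holm"` (default) or `"sidak"`.
#' @param grubbs apply Grubbs outlier screening per cell before testing
#'   (default FALSE); removals are reported, never silent.
#' @return an object of class `group_comparison`: list with `design`,
#'   `statistic`, `df`, `p`, `anova` (for ANOVA designs), `posthoc`
#'   (data.frame or NULL), `gated`, `removed` (Grubbs removals).
#' @export
group_compare <- function(data, design = c("t", "paired_t", "pearson",
                                           "one_way", "two_way", "two_way_rm"),
                          alpha = 0.05, p_adjust = c("holm", "sidak"),
                          grubbs = FALSE) {
  design <- match.arg(design)
  p_adjust <- match.arg(p_adjust)
  if (!"value" %in% names(data) || !is.numeric(data$value))
    stop("`data` must have a numeric `value` column", call. = FALSE)
  if (anyNA(data$value)) stop("non-numeric or missing outcome values", call. = FALSE)

  removed <- NULL
  if (grubbs && design %in% c("t", "one_way", "two_way")) {
    cell <- if (design == "two_way")
      interaction(data$group, data$factor2, drop = TRUE) else factor(data$group)
    keep <- unlist(lapply(split(seq_len(nrow(data)), cell), function(ix) {
      ix[grubbs_keep(data$value[ix])]
    }), use.names = FALSE)
    removed <- data[setdiff(seq_len(nrow(data)), keep), , drop = FALSE]
    data <- data[sort(keep), , drop = FALSE]
  }

  adjust <- function(p) {
    if (p_adjust == "holm") stats::p.adjust(p, "holm")
    else 1 - (1 - pmin(p, 1))^length(p)
  }

  res <- switch(design,
    t = {
      g <- split(data$value, data$group)
      if (length(g) != 2L) stop("`t` design needs exactly 2 groups", call. = FALSE)
      tt <- stats::t.test(g[[1]], g[[2]])
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, anova = NULL, posthoc = NULL, gated = NA)
    },
    paired_t = {
      g <- split(data[c("value", "subject")], data$group)
      if (length(g) != 2L) stop("paired design needs exactly 2 groups", call. = FALSE)
      a <- g[[1]][order(g[[1]]$subject), "value"]
      b <- g[[2]][order(g[[2]]$subject), "value"]
      tt <- stats::t.test(a, b, paired = TRUE)
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, anova = NULL, posthoc = NULL, gated = NA)
    },
    pearson = {
      ct <- stats::cor.test(data$value, data$value2, method = "pearson")
      list(statistic = unname(ct$estimate), df = unname(ct$parameter),
           p = ct$p.value, anova = NULL, posthoc = NULL, gated = NA)
    },
    one_way = {
      data$group <- factor(data$group)
      if (any(table(data$group) < 1L)) stop("empty cell", call. = FALSE)
      an <- stats::anova(stats::aov(value ~ group, data))
      Fv <- an$`F value`[1]; pv <- an$`Pr(>F)`[1]
      if (an$`Sum Sq`[1] <= 1e-12) { Fv <- 0; pv <- 1 }
      gated <- is.finite(pv) && pv < alpha
      ph <- NULL
      if (gated) ph <- pairwise_welch(data$value, data$group, adjust)
      list(statistic = Fv, df = an$Df[1:2], p = pv,
           anova = data.frame(effect = "group", df = an$Df[1],
                              df_res = an$Df[2], F = Fv, p = pv),
           posthoc = ph, gated = gated)
    },
    two_way = {
      data$group <- factor(data$group); data$factor2 <- factor(data$factor2)
      if (any(table(data$group, data$factor2) < 1L))
        stop("empty cell in two-way layout", call. = FALSE)
      an <- two_way_anova_table(data$value, data$group, data$factor2)
      an$effect <- c("group", "factor2", "group:factor2")
      inter <- an[3, ]
      gated <- is.finite(inter$p) && inter$p < alpha
      ph <- NULL
      if (gated) {
        rows <- lapply(levels(data$group), function(lv) {
          sub <- data[data$group == lv, ]
          pairwise_welch(sub$value, sub$factor2, identity, prefix = lv)
        })
        ph <- do.call(rbind, rows)
        ph$p_adj <- adjust(ph$p)
      }
      list(statistic = inter$F, df = c(inter$df, inter$df_res), p = inter$p,
           anova = an, posthoc = ph, gated = gated)
    },
    two_way_rm = {
      data$group <- factor(data$group); data$factor2 <- factor(data$factor2)
      data$subject <- factor(data$subject)
      tab <- table(data$subject, data$factor2)
      if (nlevels(data$factor2) != 2L || any(tab != 1L))
        stop("repeated-measures design supported only for the balanced ",
             "two-level within-subject case (each subject once per level)",
             call. = FALSE)
      fit <- stats::aov(value ~ group * factor2 + Error(subject / factor2), data)
      sm <- summary(fit)
      within <- sm[["Error: subject:factor2"]][[1]]
      inter <- within[rownames(within) == "group:factor2", ]
      Fv <- inter$`F value`; pv <- inter$`Pr(>F)`
      gated <- is.finite(pv) && pv < alpha
      ph <- NULL
      if (gated) {
        rows <- lapply(levels(data$group), function(lv) {
          sub <- data[data$group == lv, ]
          g <- split(sub[c("value", "subject")], sub$factor2)
          a <- g[[1]][order(g[[1]]$subject), "value"]
          b <- g[[2]][order(g[[2]]$subject), "value"]
          tt <- stats::t.test(a, b, paired = TRUE)
          data.frame(contrast = sprintf("%s: %s vs %s", lv,
                                        names(g)[1], names(g)[2]),
                     estimate = mean(a) - mean(b),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value)
        })
        ph <- do.call(rbind, rows)
        ph$p_adj <- adjust(ph$p)
      }
      list(statistic = unname(Fv),
           df = c(inter$Df, within["Residuals", "Df"]), p = unname(pv),
           anova = NULL, posthoc = ph, gated = gated)
    })
  structure(c(list(design = design, alpha = alpha, p_adjust = p_adjust,
                   removed = removed), res),
            class = "group_comparison")
}

pairwise_welch <- function(value, fac, adjust, prefix = NULL) {
  lv <- levels(fac)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- value[fac == pr[1]]; b <- value[fac == pr[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      data.frame(contrast = paste(c(prefix, paste(pr, collapse = " vs ")),
                                  collapse = ": "),
                 estimate = mean(a) - mean(b), t = 0,
                 df = length(a) + length(b) - 2,
                 p = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- stats::t.test(a, b)
      data.frame(contrast = paste(c(prefix, paste(pr, collapse = " vs ")),
                                  collapse = ": "),
                 estimate = mean(a) - mean(b), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust(out$p)
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> design=%s statistic=%.4g df=%s p=%.4g\n",
              x$design, x$statistic,
              paste(formatC(x$df, digits = 3, format = "fg"), collapse = ","),
              x$p))
  if (!is.null(x$posthoc)) {
    cat("post-hoc contrasts (", x$p_adjust, "-adjusted):\n", sep = "")
    print(x$posthoc, row.names = FALSE)
  } else if (isFALSE(x$gated)) {
    cat("gating effect not significant; no post-hoc contrasts emitted\n")
  }
  invisible(x)
}

# Indices to keep after iterative two-sided Grubbs screening at `alpha`.
grubbs_keep <- function(x, alpha = 0.05) {
  keep <- seq_along(x)
  repeat {
    v <- x[keep]
    n <- length(v)
    if (n < 3L) break
    g <- max(abs(v - mean(v))) / stats::sd(v)
    tcrit <- stats::qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g <= gcrit) break
    keep <- keep[-which.max(abs(v - mean(v)))]
  }
  keep
}
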