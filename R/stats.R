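# Group comparison and multivariate regression of trait tables.

starsFor <- function(p) {
  if (!is.finite(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' One-way ANOVA with Tukey HSD post hoc comparison
#'
#' Compares one trait across treatment groups with a standard one-way
#' ANOVA ([stats::aov()]) followed by Tukey's honestly-significant-
#' difference pairwise comparisons at the 95\% confidence level.
#' Significance stars follow the convention * p < 0.05, ** p < 0.01,
#' *** p < 0.001. When every group has zero internal variance the F ratio
#' is undefined and the limiting convention is reported instead (p = 1 if
#' all group means are equal, p = 0 otherwise) together with a
#' degenerate-data flag.
#'
#' @param table data.frame trait table (one row per sample).
#' @param trait name of the trait column to compare.
#' @param groupCol name of the group-label column (default `"group"`).
#' @return A [GroupComparison-class].
#' @export
anovaTukey <- function(table, trait, groupCol = "group") {
  stopifnot(is.data.frame(table), trait %in% names(table),
            groupCol %in% names(table))
  y <- table[[trait]]
  g <- factor(table[[groupCol]])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(tabulate(g) < 2)) stop("need at least 2 observations per group")
  withinVar <- vapply(split(y, g), stats::var, numeric(1))
  if (all(withinVar < .Machine$double.eps)) {
    means <- vapply(split(y, g), mean, numeric(1))
    allEqual <- max(means) - min(means) < .Machine$double.eps
    p <- if (allEqual) 1 else 0
    f <- if (allEqual) 0 else Inf
    lv <- levels(g)
    pairs <- utils::combn(lv, 2)
    tk <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                     diff = means[pairs[2, ]] - means[pairs[1, ]],
                     p_adj = ifelse(abs(means[pairs[2, ]] - means[pairs[1, ]]) <
                                      .Machine$double.eps, 1, p))
    tk$stars <- vapply(tk$p_adj, starsFor, character(1))
    rownames(tk) <- NULL
    return(new("GroupComparison", trait = trait, fStatistic = f, pValue = p,
               tukey = tk, stars = starsFor(p), degenerate = TRUE))
  }
  fit <- stats::aov(y ~ g)
  sm <- summary(fit)[[1]]
  f <- sm[["F value"]][1]
  p <- sm[["Pr(>F)"]][1]
  th <- stats::TukeyHSD(fit, conf.level = 0.95)$g
  tk <- data.frame(pair = rownames(th), diff = th[, "diff"],
                   p_adj = th[, "p adj"])
  tk$stars <- vapply(tk$p_adj, starsFor, character(1))
  rownames(tk) <- NULL
  new("GroupComparison", trait = trait, fStatistic = f, pValue = p,
      tukey = tk, stars = starsFor(p), degenerate = FALSE)
}

#' Multivariate linear regression of a growth response on trait features
#'
#' Ordinary least squares of `response ~ features` with an intercept,
#' reporting the Pearson correlation between fitted and measured response
#' values (the accuracy measure used to compare trait combinations).
#' Measured responses such as above-ground dry matter (ADM) and the canopy
#' extinction coefficient (K) are consumed from the trait table; K is never
#' derived from images. Exactly collinear features are dropped by the OLS
#' solver and reported with a warning.
#'
#' @param table data.frame trait table.
#' @param features character vector of feature column names.
#' @param response name of the measured response column.
#' @return An [MLRResult-class].
#' @seealso [defaultFeatureSets()] for the standard trait combinations.
#' @export
mlrFit <- function(table, features, response) {
  stopifnot(is.data.frame(table), all(features %in% names(table)),
            response %in% names(table))
  n <- nrow(table)
  if (n <= length(features) + 1)
    stop("need more samples than features + 1")
  X <- as.matrix(table[, features, drop = FALSE])
  if (any(apply(X, 2, stats::var) < .Machine$double.eps))
    stop("constant feature column(s): ",
         paste(features[apply(X, 2, stats::var) < .Machine$double.eps],
               collapse = ", "))
  y <- table[[response]]
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    dropped <- names(cf)[is.na(cf)]
    warning("collinear feature(s) dropped: ", paste(dropped, collapse = ", "))
    cf[is.na(cf)] <- 0
  }
  fitted <- as.numeric(stats::fitted(fit))
  r <- if (stats::sd(fitted) < 1e-300 || stats::sd(y) < 1e-300) NA_real_
  else stats::cor(fitted, y)
  new("MLRResult", features = features, coefficients = cf,
      fitted = fitted, response = y, pearsonR = r)
}

#' Standard trait combinations for growth regression
#'
#' The trait feature sets commonly regressed against above-ground dry
#' matter (`"adm"`: six sets mixing traditional traits, shape descriptors
#' and the vertical-distribution traits) and against the canopy extinction
#' coefficient (`"k"`: three sets).
#'
#' @param response `"adm"` or `"k"`.
#' @return named list of character vectors of feature column names.
#' @export
defaultFeatureSets <- function(response = c("adm", "k")) {
  response <- match.arg(response)
  if (response == "adm") {
    list(traditional = c("f_tillers", "ph", "ala_deg", "la"),
         shape_ph = c("gpar", "par", "ph"),
         shape = c("gpar", "par"),
         rhc_ph = c("rhc", "ph"),
         vertical_ph = c("fit_a", "fit_b", "rhc", "ph"),
         vertical = c("fit_a", "fit_b", "rhc"))
  } else {
    list(traditional = c("f_tillers", "ph", "ala_deg", "la"),
         shape = c("gpar", "par"),
         vertical = c("fit_a", "fit_b"))
  }
}
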