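#' Pearson and Spearman correlation, optionally on the log-log scale
#'
#' For biomass-type traits an allometric (power-law) relationship is expected,
#' so correlations are computed between natural-log-transformed variables;
#' the fitted log-log slope (the allometric exponent) is returned alongside.
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @param log_log log-transform both variables first (requires positive
#'   values).
#' @return list with `pearson_r`, `spearman_rho`, and (if `log_log`) `slope`.
#' @export
correlation_pair <- function(x, y, log_log = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite values")
  slope <- NULL
  if (log_log) {
    if (any(x <= 0) || any(y <= 0))
      stop("log-log correlation requires positive values")
    x <- log(x); y <- log(y)
    slope <- unname(coef(lm(y ~ x))[2])
  }
  out <- list(pearson_r = cor(x, y),
              spearman_rho = cor(x, y, method = "spearman"))
  if (log_log) out$slope <- slope
  out
}

harmonic_mean <- function(x) length(x) / sum(1 / x)

#' Variance components for the multi-environment trial model
#'
#' Fits the random-effects model
#' `y = mu + G + E + B(E) + GxE + R` (genotype, environment, replication
#' nested in environment, genotype-by-environment interaction, residual) and
#' returns the variance components together with two-way ANOVA significance
#' for G, E, and GxE. The default estimator is REML (lme4); `"anova"` uses
#' closed-form expected-mean-square equations (unbiased on balanced designs,
#' negative estimates truncated at zero).
#'
#' Harmonic means `t` (environments per genotype) and `r` (replications per
#' genotype within environment) are computed over per-genotype counts so
#' missing plots reduce them appropriately.
#'
#' @param table data.frame with columns `genotype_id`, `environment_id`,
#'   `replication_id`, and the trait column.
#' @param trait trait column name.
#' @param method `"reml"` or `"anova"`.
#' @return object of class `variance_components`: `var_G`, `var_E`, `var_B`,
#'   `var_GxE`, `var_R`, `t_harmonic`, `r_harmonic`, `anova_p`
#'   (named vector for G, E, GxE), `single_environment` flag.
#' @export
estimate_variance_components <- function(table, trait,
                                         method = c("reml", "anova")) {
  method <- match.arg(method)
  need <- c("genotype_id", "environment_id", "replication_id", trait)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data.frame(y = table[[trait]],
                  G = factor(table$genotype_id),
                  E = factor(table$environment_id),
                  B = factor(table$replication_id))
  d <- d[is.finite(d$y), ]
  if (nlevels(droplevels(d$G)) < 2) stop("need at least 2 genotypes")
  single_env <- nlevels(droplevels(d$E)) < 2

  tab_ge <- table(d$G, d$E)
  t_h <- harmonic_mean(rowSums(tab_ge > 0))
  r_h <- harmonic_mean(tab_ge[tab_ge > 0])

  if (single_env) {
    fit <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | G) + (1 | B), data = d,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v else 0 }
    comps <- list(var_G = get("G"), var_E = NA_real_, var_B = get("B"),
                  var_GxE = NA_real_, var_R = get("Residual"))
    warning("single environment: GxE variance is undefined")
    a <- aov(y ~ G, data = d)
    p <- summary(a)[[1]][["Pr(>F)"]]
    anova_p <- c(G = p[1], E = NA, GxE = NA)
  } else if (method == "reml") {
    fit <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | G) + (1 | E) + (1 | E:B) + (1 | G:E), data = d,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) { v <- vc$vcov[vc$grp == g]; if (length(v)) v else 0 }
    comps <- list(var_G = get("G"), var_E = get("E"), var_B = get("E:B"),
                  var_GxE = get("G:E"), var_R = get("Residual"))
    anova_p <- two_way_anova_p(d)
  } else {
    comps <- anova_components(d)
    if (is.null(comps))
      return(estimate_variance_components(table, trait, method = "reml"))
    anova_p <- two_way_anova_p(d)
  }
  comps <- lapply(comps, function(v) if (is.na(v)) v else max(v, 0))
  structure(c(comps, list(t_harmonic = t_h, r_harmonic = r_h,
                          anova_p = anova_p,
                          single_environment = single_env,
                          method = method)),
            class = "variance_components")
}

two_way_anova_p <- function(d) {
  a <- aov(y ~ G * E, data = d)
  s <- summary(a)[[1]]
  rn <- trimws(rownames(s))
  p <- s[["Pr(>F)"]]
  c(G = p[match("G", rn)], E = p[match("E", rn)], GxE = p[match("G:E", rn)])
}

# Expected-mean-square estimator for the balanced g x e x r design.
anova_components <- function(d) {
  g <- nlevels(droplevels(d$G)); e <- nlevels(droplevels(d$E))
  tab <- table(d$G, d$E)
  r <- tab[1]
  if (any(tab != r)) {
    warning("design is unbalanced; falling back to REML")
    return(NULL)
  }
  ms <- function(f) {
    a <- summary(aov(f, data = d))[[1]]
    setNames(a[["Mean Sq"]], trimws(rownames(a)))
  }
  m <- ms(y ~ G + E + E:B + G:E)
  ms_G <- m[["G"]]; ms_E <- m[["E"]]; ms_B <- m[["E:B"]]
  ms_GE <- m[["G:E"]]; ms_R <- m[["Residuals"]]
  var_R <- ms_R
  var_GxE <- (ms_GE - ms_R) / r
  var_G <- (ms_G - ms_GE) / (r * e)
  var_B <- (ms_B - ms_R) / g
  var_E <- (ms_E - ms_B - ms_GE + ms_R) / (g * r)
  list(var_G = var_G, var_E = var_E, var_B = var_B,
       var_GxE = var_GxE, var_R = var_R)
}

#' Repeatability from variance components
#'
#' Entry-mean repeatability
#' `R = var_G / (var_G + var_GxE / t + var_R / (r * t))`, or per-environment
#' repeatability `R = var_G / (var_G + var_R / r)`, where `t` is the
#' (harmonic mean) number of test environments and `r` the (harmonic mean)
#' number of replications per environment.
#'
#' @param var_G,var_GxE,var_R variance components (>= 0); alternatively pass
#'   a `variance_components` object as `var_G`.
#' @param t,r harmonic-mean environment and replication numbers (> 0);
#'   taken from the object when one is supplied.
#' @param per_env compute the within-environment form (ignores `var_GxE`,
#'   `t`).
#' @return repeatability in `[0, 1]`.
#' @export
repeatability <- function(var_G, var_GxE = 0, var_R = 0, t = NULL, r = NULL,
                          per_env = FALSE) {
  if (inherits(var_G, "variance_components")) {
    vc <- var_G
    t <- t %||% vc$t_harmonic; r <- r %||% vc$r_harmonic
    var_GxE <- if (is.na(vc$var_GxE)) 0 else vc$var_GxE
    var_R <- vc$var_R; var_G <- vc$var_G
  }
  stopifnot(var_G >= 0, var_GxE >= 0, var_R >= 0)
  if (var_G + var_GxE + var_R <= 0) stop("undefined: all components zero")
  if (per_env) {
    stopifnot(r > 0)
    var_G / (var_G + var_R / r)
  } else {
    stopifnot(t > 0, r > 0)
    var_G / (var_G + var_GxE / t + var_R / (r * t))
  }
}

#' Repeatability analysis of an observation table
#'
#' Estimates variance components for one trait and returns overall
#' (entry-mean) repeatability plus the per-environment repeatabilities, each
#' computed from a within-environment fit.
#'
#' @inheritParams estimate_variance_components
#' @return object of class `repeatability_result`: the variance components
#'   plus `R_overall` and `R_per_env` (named by environment).
#' @export
estimate_repeatability <- function(table, trait, method = "reml") {
  vc <- estimate_variance_components(table, trait, method = method)
  R_overall <- repeatability(vc)
  envs <- unique(table$environment_id)
  R_env <- vapply(envs, function(ev) {
    sub <- table[table$environment_id == ev, ]
    if (length(unique(sub$genotype_id)) < 2) return(NA_real_)
    v <- suppressWarnings(
      estimate_variance_components(sub, trait, method = "reml"))
    repeatability(v, per_env = TRUE)
  }, numeric(1))
  structure(c(unclass(vc),
              list(R_overall = R_overall,
                   R_per_env = setNames(R_env, as.character(envs)))),
            class = "repeatability_result")
}

#' Percent variance explained from a LOD score
#'
#' `PVE = 100 * (1 - 10^(-2 * LOD / n))` for a QTL with peak LOD score `LOD`
#' in a population of `n` individuals. Strictly increasing in LOD, mapping
#' `[0, Inf)` into `[0, 100)`.
#'
#' @param lod LOD score(s) (>= 0).
#' @param n number of individuals (>= 1).
#' @return percent variance explained.
#' @export
pve_from_lod <- function(lod, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(lod < 0)) stop("lod must be >= 0")
  100 * (1 - 10^(-2 * lod / n))
}

parse_marker <- function(name) {
  m <- regmatches(name, regexec("^S([0-9]+)_([0-9]+)$", name))[[1]]
  if (length(m) != 3) stop("unparseable marker name: ", name)
  list(chromosome = as.integer(m[2]), position = as.numeric(m[3]))
}

#' Width of a QTL support interval in Mb
#'
#' Marker names of the form `S{chr}_{bp}` encode chromosome and basepair
#' position; the 1.5-LOD support interval width is the distance between the
#' flanking markers, reported in megabases to 2 decimals.
#'
#' @param left_marker,right_marker flanking marker names on the same
#'   chromosome.
#' @return interval width in Mb (rounded to 2 decimals).
#' @export
lod_interval_width_mb <- function(left_marker, right_marker) {
  l <- parse_marker(left_marker); r <- parse_marker(right_marker)
  if (l$chromosome != r$chromosome)
    stop("flanking markers lie on different chromosomes")
  if (l$position > r$position)
    stop("left marker position exceeds right marker position")
  round((r$position - l$position) / 1e6, 2)
}

#' QTL-support summary for a table of QTL records
#'
#' Adds `pve` (from the LOD score and population size) and `interval_mb`
#' (from the flanking marker names) columns to a QTL table with columns
#' `qtl_name`, `chromosome`, `closest_marker`, `lod`, `left_marker`,
#' `right_marker`, and `n_individuals`.
#'
#' @param table QTL record data.frame.
#' @return the table with `pve` and `interval_mb` appended.
#' @export
qtl_support_table <- function(table) {
  need <- c("qtl_name", "lod", "left_marker", "right_marker", "n_individuals")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  table$pve <- round(pve_from_lod(table$lod, table$n_individuals), 2)
  table$interval_mb <- mapply(lod_interval_width_mb,
                              table$left_marker, table$right_marker)
  table
}
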