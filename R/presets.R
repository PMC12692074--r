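# Published group distributions used as generator presets, so simulation and
# acceptance runs need no external input.  Values are the reported mean, SD,
# maximum and minimum of each radiographic variable for 50 asymptomatic
# controls and 50 acute low back pain (ALBP) patients; angles in degrees
# (negative = lordosis), b/a dimensionless.

REFERENCE_SUMMARY <- local({
  mk <- function(group, var, mean, sd, max, min)
    data.frame(group = group, variable = var, mean = mean, sd = sd,
               max = max, min = min, stringsAsFactors = FALSE)
  rbind(
    mk("normal", "ARA_L1L5", -40.2, 9.5, -22.1, -62.9),
    mk("normal", "ARA_T12S1", -76.3, 9.9, -47.8, -97.3),
    mk("normal", "Cobb_T12S1", -65.4, 9.4, -44.2, -83.4),
    mk("normal", "SBA", 39.4, 7.2, 53.4, 23.9),
    mk("normal", "PT_S1", 50.3, 7.8, 62.1, 29.7),
    mk("normal", "API", 56.8, 11.0, 82.2, 40.6),
    mk("normal", "PTPIA", 73.9, 8.9, 92.9, 57.1),
    mk("normal", "ba_ratio", 0.389, 0.147, 0.874, 0.150),
    mk("normal", "API_minus_ARA_T12S1", -19.5, 14.4, 13.8, -47.6),
    mk("normal", "API_minus_ARA_L1L5", 16.6, 11.5, 40.0, -7.8),
    mk("normal", "API_minus_Cobb_T12S1", -8.6, 12.9, 18.9, -33.7),
    mk("albp", "ARA_L1L5", -40.9, 9.1, -14.4, -55.9),
    mk("albp", "ARA_T12S1", -77.5, 9.4, -51.4, -91.8),
    mk("albp", "Cobb_T12S1", -70.0, 10.1, -51.4, -95.5),
    mk("albp", "SBA", 44.5, 9.2, 68.2, 22.0),
    mk("albp", "PT_S1", 51.9, 7.8, 67.9, 33.9),
    mk("albp", "API", 57.4, 12.5, 86.5, 35.0),
    mk("albp", "PTPIA", 70.6, 9.5, 93.7, 55.8),
    mk("albp", "ba_ratio", 0.389, 0.230, 1.500, 0.027),
    mk("albp", "API_minus_ARA_T12S1", -20.1, 15.4, 16.3, -55.9),
    mk("albp", "API_minus_ARA_L1L5", 16.5, 13.6, 40.9, -15.3),
    mk("albp", "API_minus_Cobb_T12S1", -12.6, 10.7, 8.3, -31.3)
  )
})

# Reported Spearman correlations among the primary generative variables
# (control group / ALBP group), used to seed the copula preset.
REFERENCE_SPEARMAN <- list(
  normal = c(SBA.Cobb_T12S1 = -0.731, SBA.ba_ratio = 0.461, SBA.API = 0.492,
             Cobb_T12S1.ba_ratio = -0.596, Cobb_T12S1.API = -0.215,
             ba_ratio.API = 0.195),
  albp = c(SBA.Cobb_T12S1 = -0.862, SBA.ba_ratio = 0.143, SBA.API = 0.658,
           Cobb_T12S1.ba_ratio = -0.307, Cobb_T12S1.API = -0.539,
           ba_ratio.API = 0.001)
)

#' Published summary statistics of the reference cohorts
#'
#' @param group `"normal"`, `"albp"` or `"both"`.
#' @return data.frame with columns `group`, `variable`, `mean`, `sd`, `max`,
#'   `min`.
#' @export
reference_summary <- function(group = c("both", "normal", "albp")) {
  group <- match.arg(group)
  if (group == "both") REFERENCE_SUMMARY
  else REFERENCE_SUMMARY[REFERENCE_SUMMARY$group == group, ]
}

ref_row <- function(group, variable) {
  r <- REFERENCE_SUMMARY[REFERENCE_SUMMARY$group == group &
                           REFERENCE_SUMMARY$variable == variable, ]
  if (!nrow(r)) stop("no reference row for ", group, "/", variable,
                     call. = FALSE)
  r
}

# c(mean, sd, min, max) in the form cohort_spec() expects
ref_param <- function(group, variable, truncated = TRUE) {
  r <- ref_row(group, variable)
  if (truncated) c(r$mean, r$sd, min(r$min, r$max), max(r$min, r$max))
  else c(r$mean, r$sd)
}

#' Copula correlation preset among the generative variables
#'
#' Converts the published Spearman correlations among SBA, Cobb T12-S1, b/a
#' and API to Pearson correlations for the Gaussian copula
#' (`r = 2 sin(pi * rho_s / 6)`), clipping eigenvalues to keep the matrix
#' positive semi-definite.  The copula approximates -- it does not reproduce
#' -- the published rank-correlation structure.
#'
#' @param group `"normal"` or `"albp"`.
#' @return 4 x 4 correlation matrix with dimnames.
#' @export
reference_correlation <- function(group = c("normal", "albp")) {
  group <- match.arg(group)
  rho <- REFERENCE_SPEARMAN[[group]]
  vars <- c("SBA", "Cobb_T12S1", "ba_ratio", "API")
  M <- diag(4L); dimnames(M) <- list(vars, vars)
  for (nm in names(rho)) {
    ij <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    r <- 2 * sin(pi * rho[[nm]] / 6)
    M[ij[1L], ij[2L]] <- M[ij[2L], ij[1L]] <- r
  }
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    v <- pmax(e$values, 1e-8)
    M <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(M))
    M <- M / outer(d, d)
    dimnames(M) <- list(vars, vars)
  }
  M
}

#' Cohort spec preset at the published group distributions
#'
#' Builds a [cohort_spec()] whose generative variables (SBA, Cobb T12-S1,
#' b/a, API, PT-S1) follow the published mean/SD of each group, truncated at
#' the published min/max, with the copula correlation preset.
#'
#' @param n subjects per group.
#' @param seed integer seed.
#' @param noise_sd digitization noise SD, mm.
#' @param correlated use the [reference_correlation()] of the control group.
#' @return a [cohort_spec()].
#' @export
reference_cohort_spec <- function(n = 50L, seed, noise_sd = 0.55,
                                  correlated = TRUE) {
  vars <- c("SBA", "Cobb_T12S1", "ba_ratio", "API", "PT_S1")
  mk <- function(group) {
    g <- lapply(vars, function(v) ref_param(group, v))
    names(g) <- vars
    g
  }
  cohort_spec(normal = mk("normal"), albp = mk("albp"), n = n, seed = seed,
              noise_sd = noise_sd,
              correlation = if (correlated) reference_correlation("normal"))
}
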