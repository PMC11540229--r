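#' Expected NTC-treated growth of a wild-type aneuploid
#'
#' Multiplicative null for the drug-by-aneuploidy interaction: the expected
#' rate of the NTC-treated aneuploid is the product of its untreated rate
#' and the fractional growth-rate reduction NTC causes in the euploid,
#' computed per paired replicate:
#' `expected_i = rate(aneuploid, control)_i * rate(euploid, NTC)_i / rate(euploid, control)_i`.
#'
#' @param growth Growth table with columns `strain_id`, `background`,
#'   `amplified_chromosome`, `condition` (`control`/`NTC`), `replicate`,
#'   `rate`; replicates are same-day pairs matched by index.
#' @param chromosome Amplified chromosome of the focal aneuploid.
#' @return Data frame `replicate`, `observed` (NTC-treated aneuploid rate),
#'   `expected`, `observed_rel`, `expected_rel` (both relative to the
#'   aneuploid's untreated rate).
#' @export
expected_wt_aneuploid_ntc <- function(growth, chromosome) {
  eu_c <- paired_rates(growth, "SSD1+", NA, "control")
  eu_n <- paired_rates(growth, "SSD1+", NA, "NTC")
  an_c <- paired_rates(growth, "SSD1+", chromosome, "control")
  an_n <- paired_rates(growth, "SSD1+", chromosome, "NTC")
  reps <- Reduce(intersect, list(names(eu_c), names(eu_n), names(an_c),
                                 names(an_n)))
  if (length(reps) == 0)
    stop("no complete replicate pairs (need euploid and aneuploid, both ",
         "conditions)", call. = FALSE)
  expected <- an_c[reps] * (eu_n[reps] / eu_c[reps])
  data.frame(replicate = as.integer(reps), observed = unname(an_n[reps]),
             expected = unname(expected),
             observed_rel = unname(an_n[reps] / an_c[reps]),
             expected_rel = unname(expected / an_c[reps]))
}

#' Expected NTC-treated growth of an ssd1-null aneuploid
#'
#' Multiplicative null combining the ssd1-null effect (untreated ssd1-null
#' versus wild-type aneuploid) with the NTC effect measured in the wild-type
#' aneuploid:
#' `expected_i = (rate(ssd1d an, control)_i / rate(wt an, control)_i) * rate(wt an, NTC)_i`.
#'
#' @inheritParams expected_wt_aneuploid_ntc
#' @return Data frame as in [expected_wt_aneuploid_ntc()], with relative
#'   rates normalized to the ssd1-null aneuploid's untreated rate.
#' @export
expected_ssd1_aneuploid_ntc <- function(growth, chromosome) {
  wt_c <- paired_rates(growth, "SSD1+", chromosome, "control")
  wt_n <- paired_rates(growth, "SSD1+", chromosome, "NTC")
  mu_c <- paired_rates(growth, "ssd1d", chromosome, "control")
  mu_n <- paired_rates(growth, "ssd1d", chromosome, "NTC")
  reps <- Reduce(intersect, list(names(wt_c), names(wt_n), names(mu_c),
                                 names(mu_n)))
  if (length(reps) == 0)
    stop("no complete replicate pairs (need both backgrounds and both ",
         "conditions for ", chromosome, ")", call. = FALSE)
  expected <- (mu_c[reps] / wt_c[reps]) * wt_n[reps]
  data.frame(replicate = as.integer(reps), observed = unname(mu_n[reps]),
             expected = unname(expected),
             observed_rel = unname(mu_n[reps] / mu_c[reps]),
             expected_rel = unname(expected / mu_c[reps]))
}

paired_rates <- function(growth, background, chromosome, condition) {
  sel <- growth$background == background & growth$condition == condition &
    (if (is.na(chromosome)) is.na(growth$amplified_chromosome)
     else !is.na(growth$amplified_chromosome) &
       growth$amplified_chromosome == chromosome)
  g <- growth[sel, ]
  if (any(g$rate <= 0)) stop("growth rates must be positive", call. = FALSE)
  stats::setNames(g$rate, g$replicate)
}

#' One-tailed paired test against the multiplicative null
#'
#' Paired t-test of observed versus expected rates (alternative: observed
#' slower than expected), with significance tiers as commonly annotated
#' (`**` p < 0.01, `*` p < 0.05, `+` p < 0.1). When the paired differences
#' have (near) zero variance a variance floor is applied and flagged.
#'
#' @param observed,expected Paired per-replicate rates, or a data frame from
#'   [expected_wt_aneuploid_ntc()] / [expected_ssd1_aneuploid_ntc()] as
#'   `observed` (with `expected` left `NULL`).
#' @param alternative `"less"` (default, observed below expected) or
#'   `"two.sided"`.
#' @param tiers Significance tier cutoffs, most stringent first.
#' @param strain Optional strain label carried into the result.
#' @return Object of class `interaction_result`: strain, per-replicate
#'   deviations, mean observed/expected (absolute and relative when
#'   available), `t`, `df`, `p_value`, `tier`, `variance_floored`.
#' @export
paired_interaction_test <- function(observed, expected = NULL,
                                    alternative = c("less", "two.sided"),
                                    tiers = c(0.01, 0.05, 0.1),
                                    strain = NA_character_) {
  alternative <- match.arg(alternative)
  rel <- NULL
  if (is.data.frame(observed)) {
    df_in <- observed
    observed <- df_in$observed
    expected <- df_in$expected
    if (all(c("observed_rel", "expected_rel") %in% names(df_in)))
      rel <- c(mean(df_in$observed_rel), mean(df_in$expected_rel))
  }
  if (length(observed) != length(expected))
    stop("observed and expected must be paired per replicate", call. = FALSE)
  n <- length(observed)
  if (n < 2) stop("need >= 2 paired replicates", call. = FALSE)
  d <- observed - expected
  sd_d <- stats::sd(d)
  floored <- FALSE
  if (sd_d < 1e-12) {
    sd_d <- 1e-12
    floored <- TRUE
  }
  tt <- mean(d) / (sd_d / sqrt(n))
  p <- if (alternative == "less") stats::pt(tt, n - 1)
       else 2 * stats::pt(-abs(tt), n - 1)
  tier <- if (p < tiers[1]) "**" else if (p < tiers[2]) "*"
          else if (p < tiers[3]) "+" else "ns"
  out <- list(strain = strain, observed = observed, expected = expected,
              deviations = d, mean_observed = mean(observed),
              mean_expected = mean(expected),
              mean_observed_rel = if (is.null(rel)) NA_real_ else rel[1],
              mean_expected_rel = if (is.null(rel)) NA_real_ else rel[2],
              t = tt, df = n - 1, p_value = p, tier = tier,
              variance_floored = floored)
  class(out) <- "interaction_result"
  out
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(
    "<interaction_result> %s: observed %.4g vs expected %.4g (n = %d), one-tailed paired t p = %.3g [%s]%s\n",
    ifelse(is.na(x$strain), "strain", x$strain), x$mean_observed,
    x$mean_expected, length(x$observed), x$p_value, x$tier,
    if (x$variance_floored) " (variance floor applied)" else ""))
  invisible(x)
}

#' Run the NTC interaction test for one aneuploid strain
#'
#' @param growth Growth table (see [expected_wt_aneuploid_ntc()]).
#' @param chromosome Amplified chromosome.
#' @param genotype `"wt"` tests the wild-type aneuploid against the
#'   euploid-derived null; `"ssd1d"` tests the ssd1-null aneuploid against
#'   the null combining the ssd1-null and NTC effects.
#' @param ... Passed to [paired_interaction_test()].
#' @return An `interaction_result`.
#' @export
ntc_interaction <- function(growth, chromosome,
                            genotype = c("wt", "ssd1d"), ...) {
  genotype <- match.arg(genotype)
  pairs <- if (genotype == "wt") expected_wt_aneuploid_ntc(growth, chromosome)
           else expected_ssd1_aneuploid_ntc(growth, chromosome)
  paired_interaction_test(pairs, strain = paste0(genotype, "_", chromosome),
                          ...)
}

#' Simulate growth rates under the exact multiplicative null
#'
#' Generates a paired growth table for a euploid, a wild-type aneuploid and
#' an ssd1-null aneuploid under a model where the aneuploidy, ssd1-null and
#' NTC effects multiply exactly, with independent log-normal measurement
#' noise. Useful for calibrating [paired_interaction_test()].
#'
#' @param n_reps Paired replicates.
#' @param euploid_rate Euploid control growth rate.
#' @param aneuploidy_effect,ssd1_effect,ntc_effect Multiplicative effects
#'   (fractions of the reference rate retained).
#' @param noise_sd Log-scale standard deviation of measurement noise.
#' @param chromosome Chromosome label.
#' @param seed Seed.
#' @return Growth table with both backgrounds and both conditions.
#' @export
simulate_ntc_null <- function(n_reps = 3, euploid_rate = 0.5,
                              aneuploidy_effect = 0.8, ssd1_effect = 0.7,
                              ntc_effect = 0.8, noise_sd = 0.05,
                              chromosome = "chr12", seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(background = c("SSD1+", "ssd1d"),
                      aneuploid = c(FALSE, TRUE),
                      condition = c("control", "NTC"),
                      replicate = seq_len(n_reps),
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$background == "ssd1d" & !grid$aneuploid), ]
  mu <- euploid_rate *
    ifelse(grid$aneuploid, aneuploidy_effect, 1) *
    ifelse(grid$background == "ssd1d", ssd1_effect, 1) *
    ifelse(grid$condition == "NTC", ntc_effect, 1)
  data.frame(
    strain_id = paste0(ifelse(grid$background == "SSD1+", "wt", "ssd1d"),
                       ifelse(grid$aneuploid, paste0("_", chromosome),
                              "_euploid")),
    background = grid$background,
    amplified_chromosome = ifelse(grid$aneuploid, chromosome,
                                  NA_character_),
    condition = grid$condition, replicate = grid$replicate,
    rate = mu * exp(stats::rnorm(nrow(grid), 0, noise_sd)),
    stringsAsFactors = FALSE)
}
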