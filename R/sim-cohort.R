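# Demographic strata of the emulated cohort: proportions per group of 40,
# mirroring the recruited telemonitoring cohort (75% female; similar race
# and age distributions in both groups).
cohort_strata <- function() {
  list(
    sex = list(non_covid = c(female = 30, male = 10),
               covid = c(female = 30, male = 10)),
    race = list(non_covid = c(asian = 3, black = 3, indigenous = 0,
                              white = 17, mixed = 17),
                covid = c(asian = 3, black = 2, indigenous = 1,
                          white = 17, mixed = 17)),
    age_band = list(non_covid = c(`22-39` = 14, `40-59` = 21, `60+` = 5),
                    covid = c(`22-39` = 14, `40-59` = 21, `60+` = 5))
  )
}

# deterministic largest-remainder allocation of n units to strata
largest_remainder <- function(n, weights) {
  props <- weights / sum(weights)
  base <- floor(n * props)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(n * props - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  rep(names(weights), times = base)
}

#' Generate a synthetic volunteer roster
#'
#' Creates two equally sized study groups (previous COVID-19 diagnosis vs
#' none) whose sex, race and age-band composition follows the reference
#' cohort proportions via deterministic largest-remainder allocation, so
#' the default roster reproduces them exactly (e.g. 75% female overall).
#' The within-group order of demographic labels is shuffled under the
#' configured seed.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `volunteer_id`, `group`, `sex`,
#'   `age_band`, `race`.
#' @examples
#' sim_cohort(sim_config(seed = 1, n_per_group = 4))
#' @export
sim_cohort <- function(config) {
  stopifnot(inherits(config, "wear_config"))
  n <- config$n_per_group
  if (n == 0) {
    return(tibble::tibble(volunteer_id = character(), group = character(),
                          sex = character(), age_band = character(),
                          race = character()))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(config, "cohort"))
  strata <- cohort_strata()
  roster <- purrr::map_dfr(c("non_covid", "covid"), function(g) {
    tibble::tibble(
      group = g,
      sex = sample(largest_remainder(n, strata$sex[[g]])),
      age_band = sample(largest_remainder(n, strata$age_band[[g]])),
      race = sample(largest_remainder(n, strata$race[[g]]))
    )
  })
  roster$volunteer_id <- sprintf("V%03d", seq_len(nrow(roster)))
  dplyr::select(roster, "volunteer_id", "group", "sex", "age_band", "race")
}
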