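# Synthetic cohorts of 41-node weighted connectomes with planted,
# localized group differences and group-matched demographics, so every
# pipeline stage can be exercised end to end without imaging data.
#
# Generative model: Erdos-Renyi edge presence at `base_density` over the
# 820 node pairs; present edges carry i.i.d. log-normal fiber counts.
# Disease groups attenuate and delete edges incident to a small set of
# affected nodes (pathways crossing a region, not the region's own
# values): weight x exp(-delta |Z|), deletion probability
# min(0.5, 0.1 delta). Demographics are drawn group-independently, so
# groups are matched in expectation.

#' Configuration of the synthetic cohort generator
#'
#' Defaults mirror the reference study design: 15 subjects per class over
#' 41 nodes; AD perturbs four designated sensorimotor/piriform-like nodes
#' and MCI two of them; ages are drawn from a truncated normal centred on
#' the cohort mean (74.5 y, SD 6.7), education from the cohort's
#' empirical year levels, sex F with probability 2/3.
#'
#' @param n_per_class Subjects per group (CT, MCI, AD).
#' @param n_nodes Nodes per connectome (41 in the reference design).
#' @param base_density Probability that a node pair has a positive
#'   weight, in `[0, 1]`.
#' @param weight_meanlog,weight_sdlog Log-normal fiber-count parameters.
#' @param affected_nodes Named list (`CT`, `MCI`, `AD`) of node indices
#'   whose incident edges are perturbed.
#' @param effect_size Effect scale `delta >= 0`: weight attenuation
#'   `exp(-delta |Z|)` and deletion probability `min(0.5, 0.1 delta)`.
#' @param age_mean,age_sd,age_range Truncated-normal age law (years).
#' @param education_levels,education_probs Categorical education law
#'   (years); defaults are the reference cohort's empirical frequencies.
#' @param p_female Probability of sex `F`.
#' @param seed Integer seed; identical config + seed gives a
#'   byte-identical cohort on disk.
#' @return A list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(
    n_per_class = 15, n_nodes = 41, base_density = 0.3,
    weight_meanlog = 4, weight_sdlog = 1,
    affected_nodes = list(CT = integer(0), MCI = c(1L, 2L),
                          AD = c(1L, 2L, 4L, 27L)),
    effect_size = 2,
    age_mean = 74.5, age_sd = 6.7, age_range = c(55, 95),
    education_levels = c(4, 8, 11, 14, 15, 17, 20, 21),
    education_probs = c(5, 6, 15, 1, 13, 1, 3, 1) / 45,
    p_female = 2 / 3, seed = 1) {
  stopifnot(base_density >= 0, base_density <= 1, effect_size >= 0,
            n_per_class >= 1, n_nodes >= 2,
            all(unlist(affected_nodes) %in% seq_len(n_nodes)),
            length(education_levels) == length(education_probs))
  structure(as.list(environment()), class = "synthetic_cohort_config")
}

#' Generate one baseline connectome
#'
#' Uses the current RNG state (seed upstream, e.g. via `set.seed` or
#' [generate_cohort()]).
#'
#' @param config A [synthetic_cohort_config()].
#' @param subject_id Subject identifier.
#' @return A `connectivity_matrix`.
#' @export
generate_base_connectome <- function(config, subject_id = NA_character_) {
  n <- config$n_nodes
  npairs <- n * (n - 1) / 2
  present <- stats::runif(npairs) < config$base_density
  w <- numeric(npairs)
  w[present] <- stats::rlnorm(sum(present), config$weight_meanlog,
                              config$weight_sdlog)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- w
  m <- m + t(m)
  connectivity_matrix(m, subject_id = subject_id)
}

#' Apply a planted group effect to a connectome
#'
#' Edges incident to the group's affected nodes have their weight
#' multiplied by `exp(-delta |Z|)` (`Z` standard normal, one draw per
#' edge) and are deleted with probability `min(0.5, 0.1 delta)`; all
#' other edges are untouched and symmetry is preserved. `CT` (empty
#' affected set) and `delta = 0` leave the matrix unchanged.
#'
#' @param matrix A `connectivity_matrix`.
#' @param group Group name (`CT`, `MCI` or `AD`).
#' @param config A [synthetic_cohort_config()].
#' @return The perturbed `connectivity_matrix`.
#' @export
apply_class_effect <- function(matrix, group, config) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  affected <- config$affected_nodes[[group]] %||% integer(0)
  delta <- config$effect_size
  if (length(affected) == 0 || delta == 0) return(matrix)
  w <- matrix$weights
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  hit <- which(w[upper.tri(w)] > 0 &
                 (ut[, 1] %in% affected | ut[, 2] %in% affected))
  if (length(hit) > 0) {
    z <- stats::rnorm(length(hit))
    drop <- stats::runif(length(hit)) < min(0.5, 0.1 * delta)
    for (h in seq_along(hit)) {
      i <- ut[hit[h], 1]; j <- ut[hit[h], 2]
      val <- if (drop[h]) 0 else w[i, j] * exp(-delta * abs(z[h]))
      w[i, j] <- w[j, i] <- val
    }
  }
  connectivity_matrix(w, node_labels = matrix$node_labels,
                      subject_id = matrix$subject_id)
}

.draw_demographics <- function(n, config) {
  age <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      a <- stats::rnorm(1, config$age_mean, config$age_sd)
      if (a >= config$age_range[1] && a <= config$age_range[2]) break
    }
    age[i] <- as.integer(round(a))
  }
  edu <- sample(config$education_levels, n, replace = TRUE,
                prob = config$education_probs)
  sex <- ifelse(stats::runif(n) < config$p_female, "F", "M")
  data.frame(age = age, education = as.integer(edu), sex = sex,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' `n_per_class` subjects per group (CT, MCI, AD in that order), each a
#' baseline connectome with the group's planted effect applied, plus
#' demographics drawn identically across groups (matched in
#' expectation). Deterministic given the config (which includes the
#' seed).
#'
#' @param config A [synthetic_cohort_config()].
#' @return A `cohort` whose `"ground_truth"` attribute records the
#'   affected nodes and effect size.
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  set.seed(config$seed)
  groups <- rep(GROUP_LEVELS, each = config$n_per_class)
  ids <- sprintf("S%03d", seq_along(groups))
  matrices <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    m <- generate_base_connectome(config, subject_id = ids[i])
    matrices[[i]] <- apply_class_effect(m, groups[i], config)
  }
  names(matrices) <- ids
  demo <- .draw_demographics(length(ids), config)
  subjects <- data.frame(subject_id = ids, group = groups, demo,
                         stringsAsFactors = FALSE)
  cohort <- new_cohort(subjects, matrices)
  attr(cohort, "ground_truth") <- list(
    affected_nodes = config$affected_nodes,
    effect_size = config$effect_size, seed = config$seed
  )
  cohort
}
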