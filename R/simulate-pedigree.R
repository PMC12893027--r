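#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) receive unknown parents; every animal in
#' generation `g > 0` has a sire and dam drawn from generation `g - 1`. Each
#' female of a generation is mated to a sire sampled with replacement from
#' the males of her generation (polygyny, so paternal half-sib families
#' arise naturally) and produces `offspring_per_mating` offspring. Offspring
#' sexes alternate by birth order so that every generation keeps candidate
#' parents of both sexes.
#'
#' @param n_founders Number of founder animals (>= 2).
#' @param n_generations Number of descendant generations (>= 1).
#' @param offspring_per_mating Offspring per dam.
#' @param prop_male Proportion of males per generation (default 0.5). Dairy
#'   populations under progeny testing use few sires with large paternal
#'   half-sib families; a small `prop_male` emulates that structure.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A tibble with columns `animal_id`, `sire_id`, `dam_id` (`NA` for
#'   unknown founder parents), `sex` (`"M"`/`"F"`) and `generation`, ordered
#'   so parents always precede their offspring.
#' @examples
#' simulate_pedigree(n_founders = 4, n_generations = 2, seed = 1)
#' @export
simulate_pedigree <- function(n_founders = 100, n_generations = 3,
                              offspring_per_mating = 2, prop_male = 0.5,
                              seed = 1L) {
  if (n_founders < 2) abort("`n_founders` must be at least 2.")
  if (n_generations < 1) abort("`n_generations` must be at least 1.")
  if (offspring_per_mating < 1) abort("`offspring_per_mating` must be >= 1.")
  if (prop_male <= 0 || prop_male >= 1) abort("`prop_male` must be in (0, 1).")
  withr::local_seed(seed)

  sexes <- function(n) {
    n_m <- max(1L, round(n * prop_male))
    ## interleave so both sexes appear even in tiny generations
    s <- rep("F", n)
    s[unique(pmin(n, ceiling(seq(1, n, length.out = n_m))))] <- "M"
    s
  }
  id <- function(i) sprintf("A%06d", i)
  next_id <- 1L
  founders <- tibble(
    animal_id = id(seq_len(n_founders)),
    sire_id = NA_character_, dam_id = NA_character_,
    sex = sexes(n_founders),
    generation = 0L
  )
  next_id <- n_founders + 1L
  gens <- list(founders)

  for (g in seq_len(n_generations)) {
    prev <- gens[[g]]
    sires <- prev$animal_id[prev$sex == "M"]
    dams <- prev$animal_id[prev$sex == "F"]
    if (length(sires) < 1 || length(dams) < 1) {
      abort("need at least one male and one female candidate parent.")
    }
    sire_of_dam <- sample(sires, length(dams), replace = TRUE)
    n_off <- length(dams) * offspring_per_mating
    off <- tibble(
      animal_id = id(seq(next_id, length.out = n_off)),
      sire_id = rep(sire_of_dam, each = offspring_per_mating),
      dam_id = rep(dams, each = offspring_per_mating),
      sex = sexes(n_off),
      generation = g
    )
    next_id <- next_id + n_off
    gens[[g + 1]] <- off
  }
  bind_rows(gens)
}

#' Validate pedigree structure
#'
#' Checks ID uniqueness, that every named parent appears as an animal
#' earlier in the table, and (implied by the ordering check) acyclicity.
#' @param pedigree A pedigree tibble as from [simulate_pedigree()].
#' @return The pedigree, invisibly; errors describe any violation.
#' @export
validate_pedigree <- function(pedigree) {
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(pedigree)))
  if (anyDuplicated(pedigree$animal_id)) {
    abort("duplicated animal IDs in pedigree.")
  }
  pos <- setNames(seq_len(nrow(pedigree)), pedigree$animal_id)
  for (col in c("sire_id", "dam_id")) {
    par <- pedigree[[col]]
    known <- !is.na(par)
    missing <- setdiff(par[known], names(pos))
    if (length(missing)) {
      abort(sprintf("parents not present as animals: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    if (any(pos[par[known]] >= pos[pedigree$animal_id[known]])) {
      abort("pedigree is not sorted parents-before-offspring (possible cycle).")
    }
  }
  invisible(pedigree)
}
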