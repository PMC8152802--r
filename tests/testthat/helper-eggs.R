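# build minimal egg records from per-status cohort sizes
eggs_from_counts <- function(iso_year, iso_week, H = 0, E = 0, P = 0, U = 0,
                             X = 0, site_id = "S", trap_id = "T01") {
  status <- rep(
    c("HATCHED", "EMBRYONATED_UNHATCHED", "PARTIAL_EMBRYO", "UNFERTILISED",
      "EXCLUDED"),
    times = c(H, E, P, U, X)
  )
  n <- length(status)
  if (n == 0) {
    return(tibble::tibble(
      egg_id = character(), site_id = character(), trap_id = character(),
      collection_date = as.Date(character()), status = character()
    ))
  }
  tibble::tibble(
    egg_id = sprintf("%d-%02d-%04d", iso_year, iso_week, seq_len(n)),
    site_id = site_id,
    trap_id = trap_id,
    collection_date = iso_week_start(iso_year, iso_week) + 6L,
    status = status
  )
}

# attach triplicate morphometry to an egg tibble (constant reps)
with_morph <- function(eggs, length_um, width_um) {
  eggs$length_rep1_um <- length_um
  eggs$length_rep2_um <- length_um
  eggs$length_rep3_um <- length_um
  eggs$width_rep1_um <- width_um
  eggs$width_rep2_um <- width_um
  eggs$width_rep3_um <- width_um
  eggs
}

# small, fast synthetic season for pipeline tests
small_sim_config <- function(seed = 1L, ...) {
  sim_config(
    seed = seed,
    peak1_height = 400, peak2_height = 150, baseline_eggs = 10,
    morph_fraction = 0.3,
    ...
  )
}
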