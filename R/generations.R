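#' The 12-generation temperature-shift design
#'
#' The experimental backbone of the pipeline is a fixed 12-generation
#' temperature-shift scheme: three generations at 15 degrees C
#' (`15C-G1..G3`), six at 23 degrees C (`23C-G1..G6`), then three more at
#' 15 degrees C after the stress (`p15C-G1..G3`, "p" for post-heat-stress).
#' Generation labels form a closed, ordered vocabulary; the label alone
#' determines the culture temperature.
#'
#' @return `generation_levels()` returns the 12 ordered generation labels.
#' @examples
#' generation_levels()
#' generation_temperature(c("15C-G2", "23C-G5", "p15C-G1"))
#' @export
generation_levels <- function() {
  c(paste0("15C-G", 1:3), paste0("23C-G", 1:6), paste0("p15C-G", 1:3))
}

#' @rdname generation_levels
#' @param generation character vector of generation labels.
#' @return `generation_temperature()` returns the culture temperature
#'   (15 or 23, degrees C) implied by each label.
#' @export
generation_temperature <- function(generation) {
  stopifnot(all(generation %in% generation_levels()))
  ifelse(grepl("^23C", generation), 23L, 15L)
}

#' @rdname generation_levels
#' @return `generation_index()` returns the chronological index (1..12) of
#'   each label.
#' @export
generation_index <- function(generation) {
  idx <- match(generation, generation_levels())
  if (anyNA(idx)) {
    stop("unknown generation label(s): ",
         paste(unique(generation[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Temperature condition groups used for differential calling
#'
#' Mean expression at each temperature is computed over fixed generation
#' groups: the 15 C group uses all three pre-stress 15 C generations; the
#' 23 C group uses generations 2-6 at 23 C. `23C-G1` is excluded because
#' those animals experienced both temperatures within one life cycle
#' (the shift happened at embryogenesis), and the post-stress `p15C`
#' generations are excluded from the 15 C group to avoid carry-over effects.
#'
#' @return Named list of character vectors of generation labels, with
#'   entries `G15`, `G23` and `Gp15`.
#' @examples
#' condition_groups()$G23   # note 23C-G1 is absent
#' @export
condition_groups <- function() {
  list(
    G15  = paste0("15C-G", 1:3),
    G23  = paste0("23C-G", 2:6),
    Gp15 = paste0("p15C-G", 1:3)
  )
}

#' Chronological phases for small RNA analysis
#'
#' The 12 generations are divided evenly into four chronological phases of
#' three generations each: phase I (pre-stress 15 C), phases II and III
#' (early and late 23 C), and phase IV (post-stress 15 C). Antisense siRNA
#' levels are averaged within each phase.
#'
#' @return Named list `I`, `II`, `III`, `IV` of generation-label vectors
#'   which partition [generation_levels()].
#' @examples
#' phase_groups()
#' @export
phase_groups <- function() {
  list(
    I   = paste0("15C-G", 1:3),
    II  = paste0("23C-G", 1:3),
    III = paste0("23C-G", 4:6),
    IV  = paste0("p15C-G", 1:3)
  )
}

#' Validate a sample metadata table
#'
#' Sample metadata travels in a sidecar table with one row per sequencing
#' library. Checks the closed vocabularies (genotype, generation, library
#' type, repeat), uniqueness of sample ids, and that the recorded
#' temperature (when present) matches the one implied by the generation
#' label.
#'
#' @param meta data.frame with columns `sample_id`, `genotype`
#'   (`WT`/`hrde1`), `generation` (see [generation_levels()]),
#'   `repeat_id` (1 or 2) and `library`
#'   (`mRNA`, `sRNA`, `chip_pol2`, `chip_h3k9me3`, `chip_input`).
#'   An optional `temperature` column is cross-checked.
#' @return The validated data.frame with a `temperature` column filled in
#'   from the generation labels.
#' @export
validate_sample_meta <- function(meta) {
  req <- c("sample_id", "genotype", "generation", "repeat_id", "library")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  if (!all(meta$genotype %in% c("WT", "hrde1"))) {
    stop("genotype must be 'WT' or 'hrde1'")
  }
  bad_gen <- setdiff(unique(meta$generation), generation_levels())
  if (length(bad_gen)) stop("unknown generation label(s): ", paste(bad_gen, collapse = ", "))
  if (!all(meta$repeat_id %in% c(1L, 2L))) stop("repeat_id must be 1 or 2")
  libs <- c("mRNA", "sRNA", "chip_pol2", "chip_h3k9me3", "chip_input")
  if (!all(meta$library %in% libs)) {
    stop("library must be one of: ", paste(libs, collapse = ", "))
  }
  tmp <- generation_temperature(meta$generation)
  if ("temperature" %in% names(meta)) {
    if (!all(meta$temperature == tmp)) {
      stop("temperature column disagrees with generation labels for: ",
           paste(meta$sample_id[meta$temperature != tmp], collapse = ", "))
    }
  }
  meta$temperature <- tmp
  meta$repeat_id <- as.integer(meta$repeat_id)
  meta
}
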