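#' Surgical step vocabularies
#'
#' A step vocabulary is a tibble with columns `code` (integer label used in
#' annotation files), `name` and `core` (mandatory step flag). The default
#' vocabulary models endoscopic transsphenoidal pituitary surgery: 8 core and
#' 6 optional steps, with haemostasis (code 8) repeatable at any point of the
#' workflow.
#'
#' @return A tibble with columns `code`, `name`, `core`.
#' @examples
#' pituitary_steps()
#' @export
pituitary_steps <- function() {
  tibble::tibble(
    code = 1:14,
    name = c(
      "nasal_corridor_creation",
      "anterior_sphenoidotomy",
      "septum_displacement",
      "sphenoid_sinus_clearance",
      "sellotomy",
      "durotomy",
      "tumour_excision",
      "haemostasis",
      "turbinate_lateralisation",
      "synthetic_graft_placement",
      "fat_graft_placement",
      "gasket_seal_construct",
      "dural_sealant",
      "nasal_packing"
    ),
    core = c(rep(TRUE, 8), rep(FALSE, 6))
  )
}

#' Default surgical instrument vocabulary
#'
#' Eighteen instruments, coded 1..18, used by the workflow simulator's
#' per-step instrument emissions and by the instrument-augmented
#' sequence-matching estimator.
#'
#' @return A tibble with columns `code`, `name`.
#' @export
pituitary_instruments <- function() {
  tibble::tibble(
    code = 1:18,
    name = c(
      "freer_elevator", "cottle_elevator", "monopolar_cautery",
      "bipolar_forceps", "kerrison_rongeur", "high_speed_drill",
      "blakesley_forceps", "ring_curette", "cup_forceps",
      "suction_tip", "micro_doppler", "dural_scissors",
      "pituitary_rongeur", "irrigation_syringe", "haemostatic_foam",
      "graft_applicator", "sealant_applicator", "nasal_speculum"
    )
  )
}

#' Read or write a step vocabulary as JSON
#'
#' The on-disk form is a JSON array of objects `{code, name, core}`.
#'
#' @param path File path.
#' @param vocabulary A vocabulary tibble (see [pituitary_steps()]).
#' @return `read_vocabulary()` returns a vocabulary tibble;
#'   `write_vocabulary()` returns `path` invisibly.
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::fromJSON(path)
  out <- tibble::as_tibble(x)
  if (!all(c("code", "name") %in% names(out))) {
    abort("vocabulary JSON must contain fields 'code' and 'name'")
  }
  out$code <- as.integer(out$code)
  if (is.null(out$core)) out$core <- TRUE
  out
}

#' @rdname read_vocabulary
#' @export
write_vocabulary <- function(vocabulary, path) {
  jsonlite::write_json(vocabulary, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
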