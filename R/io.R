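# Sweep-table serialization: CSV results with a JSON metadata sidecar.

#' Write a sweep table to CSV
#'
#' Columns are written in the documented order of [run_sweep()] with
#' floating-point values at 12 significant digits. An optional metadata
#' JSON (config echo, package version, master seed) is written alongside
#' so a sweep can be re-run exactly.
#'
#' @param records A sweep tibble from [run_sweep()].
#' @param path Output CSV path; its directory must exist.
#' @param config Optional [sweep_config()] echoed into the metadata file.
#' @param meta_path Optional path for the metadata JSON; defaults to
#'   `path` with a `.meta.json` extension when `config` is supplied.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, config = NULL, meta_path = NULL) {
  stopifnot(is.data.frame(records))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir)
  }
  cols <- intersect(sweep_record_columns(), names(records))
  out <- records[, c(cols, setdiff(names(records), cols)), drop = FALSE]
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_,
                       formatC(x, digits = 12, format = "g"))
  ))
  readr::write_csv(out, path, na = "")
  if (!is.null(config) || !is.null(meta_path)) {
    if (is.null(meta_path)) {
      meta_path <- sub("\\.csv$", "", path)
      meta_path <- paste0(meta_path, ".meta.json")
    }
    meta <- list(
      package = "sdturnover",
      version = as.character(utils::packageVersion("sdturnover")),
      master_seed = if (!is.null(config)) config$seed,
      n_records = nrow(records),
      config = if (!is.null(config)) serialize_config(config)
    )
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

serialize_config <- function(config) {
  tpl <- config$template
  list(transition = tpl$transition, epi_type = tpl$epi_type,
       epi_partner = tpl$epi_partner,
       n_replicates = config$n_replicates,
       s_range = config$s_range, eps_range = config$eps_range,
       seed = config$seed,
       burn_in = tpl$burn_in, total_generations = tpl$total_generations,
       intro_freq = tpl$intro_freq, init_freq = tpl$init_freq,
       rates = unclass(tpl$rates), outcome_read = tpl$outcome_read)
}

#' Read a sweep table written by [write_results()]
#'
#' @param path CSV path.
#' @return A sweep tibble with the documented column types; `outcome`
#'   bits are recovered exactly and floats to the written 12 significant
#'   digits.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    stop("no such results file: ", path)
  }
  spec <- readr::cols(
    transition = readr::col_character(),
    epi_type = readr::col_character(),
    epi_partner = readr::col_character(),
    replicate = readr::col_integer(),
    sub_seed = readr::col_integer(),
    outcome = readr::col_integer(),
    generations_run = readr::col_integer(),
    error = readr::col_character(),
    .default = readr::col_double()
  )
  readr::read_csv(path, col_types = spec, na = "")
}
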