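#' Export a report bundle as CSV files
#'
#' Writes every tabular component of a validation or super-population
#' report to `dir`, one CSV per table. Each file starts with a comment
#' line carrying a hash of the report's configuration (and the
#' configuration's seed where present), so any two runs with identical
#' configuration produce byte-identical outputs and outputs can be
#' traced to their settings.
#'
#' @param report An `szr_validation_report` or `szr_superpop_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg_hash <- rlang::hash(report$config)
  tables <- report_tables(report)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, open = "wt")
    writeLines(paste0("# config_hash: ", cfg_hash), con)
    close(con)
    tab <- dplyr::mutate(
      tibble::as_tibble(tables[[nm]]),
      dplyr::across(dplyr::where(is.factor), as.character)
    )
    readr::write_csv(tab, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
    paths <- c(paths, path)
  }
  meta <- file.path(dir, "config.json")
  writeLines(to_json(c(report$config, list(config_hash = cfg_hash))),
             meta)
  invisible(c(paths, meta))
}

report_tables <- function(report) {
  if (inherits(report, "szr_validation_report")) {
    calib <- purrr::imap_dfr(report$calibration, function(tab, nm) {
      dplyr::mutate(tibble::as_tibble(tab), dataset = nm, .before = 1)
    })
    list(
      concordance = report$concordance,
      calibration = calib,
      risk_group_hazard_ratios = report$risk_groups$hr_table,
      risk_group_km = report$risk_groups$km,
      low_risk_km = report$low_risk_km
    )
  } else if (inherits(report, "szr_superpop_report")) {
    sens <- purrr::imap_dfr(report$sensitivity, function(tab, nm) {
      dplyr::mutate(tibble::as_tibble(tab), analysis = nm, .before = 1)
    })
    list(
      effect_estimates = report$estimates,
      sensitivity_estimates = sens,
      risk_table = report$risk_table,
      risk_profiles = report$profiles,
      threshold_crossings = report$crossings
    )
  } else {
    abort("unknown report type")
  }
}

# minimal JSON writer for flat config lists (avoids a hard jsonlite
# dependency in the package itself)
to_json <- function(x) {
  enc <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v)) {
      return(paste0("[", paste(vapply(v, enc, character(1)),
                               collapse = ","), "]"))
    }
    if (length(v) > 1) {
      return(paste0("[", paste(vapply(v, function(e) enc(e),
                                      character(1)), collapse = ","),
                    "]"))
    }
    if (is.character(v)) return(paste0("\"", v, "\""))
    if (is.logical(v)) return(tolower(as.character(v)))
    as.character(v)
  }
  paste0("{", paste(vapply(seq_along(x), function(i) {
    paste0("\"", names(x)[i], "\":", enc(x[[i]]))
  }, character(1)), collapse = ","), "}")
}
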