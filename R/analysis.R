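#' Plateau summary of a time course
#'
#' Applies [detect_steady_state()] to each requested series and collects the
#' plateau values and attainment times into one table. Series that never
#' settle carry their final value with `attained = FALSE`.
#'
#' @param tc An `anlsim_timecourse`.
#' @param keys Character vector of state keys (`"ATP@Nm"`, ...).
#' @param window,rel_tol Passed to [detect_steady_state()].
#' @return Tibble, one row per key.
#' @export
summarize_timecourse <- function(tc, keys, window = 25, rel_tol = 0.01) {
  dplyr::bind_rows(lapply(keys, function(k) {
    detect_steady_state(tc, k, window = window, rel_tol = rel_tol)
  }))
}

#' Compare the two model variants across scenarios
#'
#' For each scenario present in both variants' experiment sets, computes the
#' plateau of each requested series under the classical and the
#' lactate-shuttle variant and their fold-change (ANLSH / classical), plus
#' the across-scenario mean fold-change per series. Fold-changes are left
#' `NA` where the classical plateau is not positive.
#'
#' @param experiments List of `anlsim_timecourse` objects covering both
#'   variants; scenarios are matched by name and must pair up.
#' @param keys Series to compare (default: neuron mitochondrial ATP).
#' @param window,rel_tol Plateau detection settings.
#' @return An `anlsim_comparison`: `$table` has one row per (key, scenario)
#'   with both plateaus, attainment times and the fold-change; `$mean_fold`
#'   has the across-scenario mean per key.
#' @export
compare_models <- function(experiments, keys = "ATP@Nm",
                           window = 25, rel_tol = 0.01) {
  variants <- vapply(experiments, function(e) e$variant, "")
  scen <- vapply(experiments, function(e) e$scenario$name, "")
  digests <- unique(vapply(experiments, function(e) e$digest, ""))
  rows <- list()
  for (s in unique(scen)) {
    i_c <- which(variants == "classical" & scen == s)
    i_a <- which(variants == "anlsh" & scen == s)
    if (length(i_c) != 1 || length(i_a) != 1) {
      stop(sprintf("scenario '%s' is not paired across variants", s),
           call. = FALSE)
    }
    for (k in keys) {
      pc <- detect_steady_state(experiments[[i_c]], k, window, rel_tol)
      pa <- detect_steady_state(experiments[[i_a]], k, window, rel_tol)
      rows[[length(rows) + 1]] <- tibble::tibble(
        key = k, scenario = s,
        classical_plateau = pc$plateau, anlsh_plateau = pa$plateau,
        classical_attained = pc$attained, anlsh_attained = pa$attained,
        classical_time = pc$time_attained, anlsh_time = pa$time_attained,
        fold_change = ifelse(pc$plateau > 0, pa$plateau / pc$plateau, NA_real_)
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  mean_fold <- dplyr::summarise(
    dplyr::group_by(tab, .data$key),
    mean_fold_change = mean(.data$fold_change), .groups = "drop")
  structure(list(table = tab, mean_fold = mean_fold,
                 provenance = digests),
            class = "anlsim_comparison")
}

#' @export
print.anlsim_comparison <- function(x, ...) {
  cat("<anlsim_comparison>\n")
  print(x$table)
  cat("across-scenario mean fold-change (ANLSH / classical):\n")
  print(x$mean_fold)
  invisible(x)
}

#' @export
tidy.anlsim_comparison <- function(x, ...) x$table

#' @export
glance.anlsim_comparison <- function(x, ...) {
  tibble::tibble(
    n_scenarios = length(unique(x$table$scenario)),
    n_series = length(unique(x$table$key)),
    mean_fold_change = x$mean_fold$mean_fold_change[1],
    provenance = paste(x$provenance, collapse = ";")
  )
}

#' Write / read a comparison report
#'
#' Lossless serialization of the comparison table and mean fold-changes.
#' CSV writes the long table with the provenance digest in a comment
#' header; JSON nests table, means and provenance in one document. Both
#' renderings carry identical numeric cells.
#'
#' @param report An `anlsim_comparison`.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(table = report$table, mean_fold = report$mean_fold,
           provenance = report$provenance),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# provenance: %s", paste(report$provenance, collapse = ";")),
               con)
    utils::write.csv(report$table, con, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    structure(list(table = tibble::as_tibble(raw$table),
                   mean_fold = tibble::as_tibble(raw$mean_fold),
                   provenance = raw$provenance),
              class = "anlsim_comparison")
  } else {
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    tab <- tibble::as_tibble(
      utils::read.csv(text = paste(lines[-hdr], collapse = "\n")))
    mean_fold <- dplyr::summarise(
      dplyr::group_by(tab, .data$key),
      mean_fold_change = mean(.data$fold_change), .groups = "drop")
    structure(list(table = tab, mean_fold = mean_fold,
                   provenance = sub("^# provenance: ", "", lines[hdr])),
              class = "anlsim_comparison")
  }
}
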