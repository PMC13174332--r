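#' Validation reports with normative severities
#'
#' Structural and content checks throughout the package report their results
#' as a *validation report*: a tibble of findings with the normative
#' severities used by data-standard documents. A finding with severity
#' `"MUST"` marks a violation of a hard requirement; `"RECOMMENDED"` marks a
#' desirable component that is absent or incomplete; `"INFO"` is advisory.
#' An object is *conformant* when its report contains zero `MUST` findings.
#'
#' @param severity Character vector of severities (`MUST`, `RECOMMENDED`,
#'   `INFO`).
#' @param code Short machine-readable finding code.
#' @param path Location of the finding (a slot, column, cell id, entity id).
#' @param message Human-readable description.
#' @return A tibble of class `ait_validation` with columns `severity`,
#'   `code`, `path`, `message`.
#' @examples
#' rep <- validation_report("MUST", "duplicate_cell_id", "obs/c1", "cell id 'c1' duplicated")
#' is_conformant(rep)
#' @export
validation_report <- function(severity = character(), code = character(),
                              path = character(), message = character()) {
  stopifnot(all(severity %in% c("MUST", "RECOMMENDED", "INFO")))
  out <- tibble(
    severity = as.character(severity),
    code = as.character(code),
    path = as.character(path),
    message = as.character(message)
  )
  class(out) <- c("ait_validation", class(out))
  out
}

finding <- function(severity, code, path, message) {
  validation_report(severity, code, path, message)
}

bind_findings <- function(...) {
  out <- bind_rows(...)
  class(out) <- unique(c("ait_validation", class(out)))
  out
}

#' @rdname validation_report
#' @param report A validation report.
#' @export
is_conformant <- function(report) {
  stopifnot(inherits(report, "ait_validation") || is.data.frame(report))
  !any(report$severity == "MUST")
}

#' @export
glance.ait_validation <- function(x, ...) {
  tibble(
    n_findings = nrow(x),
    n_must = sum(x$severity == "MUST"),
    n_recommended = sum(x$severity == "RECOMMENDED"),
    n_info = sum(x$severity == "INFO"),
    conformant = is_conformant(x)
  )
}

#' @export
print.ait_validation <- function(x, ...) {
  status <- if (is_conformant(x)) "conformant (no MUST findings)" else "NOT conformant"
  cat(sprintf("<validation report> %d finding(s); %s\n", nrow(x), status))
  if (nrow(x) > 0) print(as_tibble(unclass_report(x)), ...)
  invisible(x)
}

unclass_report <- function(x) {
  class(x) <- setdiff(class(x), "ait_validation")
  x
}
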