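#' ADME oral-activity criteria
#'
#' The eight-criterion screen for orally active compounds: Lipinski's
#' rule of five (molecular weight, ALogP, H-bond donors/acceptors, all
#' strict) extended by oral bioavailability, drug-likeness (both
#' inclusive), Caco-2 permeability (strict) and rotatable bond count
#' (inclusive).  Defaults are the conventional cutoffs
#' `MW < 500`, `ALogP < 5`, `Hdon < 5`, `Hacc < 10`, `OB >= 30`,
#' `DL >= 0.18`, `Caco-2 > -0.4`, `RBN <= 10`.  Operator strictness
#' matters at the boundaries: a compound with `DL` exactly 0.18 passes,
#' one with `MW` exactly 500 fails.
#'
#' @param mw,alogp,hdon,hacc,ob,dl,caco2,rbn threshold values.
#' @param operators named character vector of comparison operators (from
#'   `<`, `<=`, `>`, `>=`), one per property.
#' @param missing_policy what to do when a compound lacks a property:
#'   `"fail"` (default; an uninformed compound cannot be declared orally
#'   active), `"pass"`, or `"error"`.
#' @return an object of class `adme_criteria`.
#' @export
adme_criteria <- function(mw = 500, alogp = 5, hdon = 5, hacc = 10,
                          ob = 30, dl = 0.18, caco2 = -0.4, rbn = 10,
                          operators = c(mw = "<", alogp = "<", hdon = "<",
                                        hacc = "<", ob = ">=", dl = ">=",
                                        caco2 = ">", rbn = "<="),
                          missing_policy = c("fail", "pass", "error")) {
  missing_policy <- match.arg(missing_policy)
  thresholds <- c(mw = mw, alogp = alogp, hdon = hdon, hacc = hacc,
                  ob = ob, dl = dl, caco2 = caco2, rbn = rbn)
  if (!setequal(names(operators), ADME_PROPERTIES)) {
    stop("operators must be given for all eight ADME properties")
  }
  bad <- setdiff(unique(operators), c("<", "<=", ">", ">="))
  if (length(bad)) stop("unsupported operator(s): ", paste(bad, collapse = ", "))
  structure(list(thresholds = thresholds,
                 operators = operators[ADME_PROPERTIES],
                 missing_policy = missing_policy),
            class = "adme_criteria")
}

#' @export
print.adme_criteria <- function(x, ...) {
  cat("<adme_criteria>\n")
  for (p in ADME_PROPERTIES) {
    cat(sprintf("  %-6s %s %s\n", p, x$operators[[p]], x$thresholds[[p]]))
  }
  cat("  missing_policy:", x$missing_policy, "\n")
  invisible(x)
}

#' Test one compound against the ADME criteria
#'
#' @param record a one-row compound `data.frame` or a named list with
#'   the eight ADME properties.
#' @param criteria an [adme_criteria()] object.
#' @return list with `pass` (logical conjunction of the eight verdicts)
#'   and `verdicts` (named logical vector, one entry per property, for
#'   auditing).
#' @export
is_orally_active <- function(record, criteria = adme_criteria()) {
  stopifnot(inherits(criteria, "adme_criteria"))
  verdicts <- vapply(ADME_PROPERTIES, function(p) {
    value <- record[[p]]
    if (is.null(value) || length(value) != 1L || is.na(value)) {
      switch(criteria$missing_policy,
             fail = return(FALSE),
             pass = return(TRUE),
             error = stop("missing ADME property '", p, "' for compound ",
                          record[["compound_id"]] %||% "<unknown>"))
    }
    do.call(criteria$operators[[p]],
            list(as.numeric(value), criteria$thresholds[[p]]))
  }, logical(1))
  list(pass = all(verdicts), verdicts = verdicts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen a compound table for oral activity
#'
#' Applies [is_orally_active()] to every row and reports the passing
#' compounds, the full per-compound/per-criterion verdict matrix and the
#' per-herb counts of passers.  Deterministic and order-independent; the
#' screen is idempotent (screening the passing set returns it unchanged).
#'
#' @param records compound `data.frame` (see [read_compound_table()]).
#' @param criteria an [adme_criteria()] object.
#' @return an object of class `screen_result`: list with `passing`
#'   (subset of `records`), `verdicts` (logical matrix, compounds x
#'   criteria, with a final `pass` column) and `per_herb_counts`
#'   (named integer vector over herbs with at least one passer).
#' @export
screen_compounds <- function(records, criteria = adme_criteria()) {
  if (nrow(records) == 0L) {
    return(structure(list(passing = records,
                          verdicts = matrix(logical(), 0, 9,
                                            dimnames = list(NULL, c(ADME_PROPERTIES, "pass"))),
                          per_herb_counts = integer()),
                     class = "screen_result"))
  }
  per <- lapply(seq_len(nrow(records)), function(i) {
    is_orally_active(records[i, , drop = FALSE], criteria)
  })
  verdicts <- t(vapply(per, function(x) x$verdicts, logical(8)))
  pass <- vapply(per, function(x) x$pass, logical(1))
  verdicts <- cbind(verdicts, pass = pass)
  rownames(verdicts) <- records$compound_id
  passing <- records[pass, , drop = FALSE]
  rownames(passing) <- NULL
  counts <- table(passing$herb_source)
  per_herb <- stats::setNames(as.integer(counts), names(counts))
  structure(list(passing = passing, verdicts = verdicts,
                 per_herb_counts = per_herb),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", nrow(x$passing), " of ", nrow(x$verdicts),
      " compounds orally active\n", sep = "")
  if (length(x$per_herb_counts)) {
    cat("  per herb: ",
        paste(names(x$per_herb_counts), x$per_herb_counts,
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Export the per-compound, per-criterion audit table
#'
#' One row per compound x criterion with the compared value, threshold,
#' operator and verdict.
#'
#' @param result a `screen_result`.
#' @param records the compound table that was screened.
#' @param criteria the criteria used.
#' @param path optional output TSV path.
#' @return the audit `data.frame` (invisibly if `path` is given).
#' @export
screen_audit_table <- function(result, records, criteria = adme_criteria(),
                               path = NULL) {
  stopifnot(inherits(result, "screen_result"))
  rows <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    data.frame(compound_id = records$compound_id[i],
               name = records$name[i],
               property = ADME_PROPERTIES,
               value = as.numeric(unlist(records[i, ADME_PROPERTIES])),
               operator = unname(criteria$operators[ADME_PROPERTIES]),
               threshold = unname(criteria$thresholds[ADME_PROPERTIES]),
               verdict = unname(result$verdicts[i, ADME_PROPERTIES]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
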