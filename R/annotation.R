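ANNOTATION_NAMESPACES <- c("BP", "MF", "CC", "KEGG")

#' Construct an annotation term database
#'
#' Holds GO/KEGG-style annotation terms (term id, human-readable name,
#' namespace, member genes) and the background of all annotated genes.
#' Every term's genes must lie inside the background and term sizes must
#' be at least one.
#'
#' @param terms `data.frame` with columns `term_id`, `term_name`,
#'   `namespace` (one of `BP`, `MF`, `CC`, `KEGG`) and a list column
#'   `genes` of character vectors.
#' @param background optional character vector of background genes;
#'   defaults to the union of all term genes.
#' @return an object of class `annotation_db`.
#' @export
annotation_db <- function(terms, background = NULL) {
  stopifnot(is.data.frame(terms),
            all(c("term_id", "term_name", "namespace", "genes") %in% names(terms)))
  if (nrow(terms) == 0L) stop("annotation database has no terms")
  bad_ns <- setdiff(unique(terms$namespace), ANNOTATION_NAMESPACES)
  if (length(bad_ns)) stop("unknown namespace(s): ", paste(bad_ns, collapse = ", "))
  terms$genes <- lapply(terms$genes, function(g) sort(unique(toupper(g))))
  sizes <- lengths(terms$genes)
  if (any(sizes < 1L)) stop("every term must contain at least one gene")
  universe <- sort(unique(unlist(terms$genes)))
  if (is.null(background)) {
    background <- universe
  } else {
    background <- sort(unique(toupper(background)))
    if (!all(universe %in% background)) {
      stop("term genes outside the declared background")
    }
  }
  rownames(terms) <- NULL
  structure(list(terms = terms, background = background),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("<annotation_db> ", nrow(x$terms), " terms (",
      paste(unique(x$terms$namespace), collapse = "/"), "), background ",
      length(x$background), " genes\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One term per line: `term_id <tab> term_name <tab> gene1 <tab> gene2 ...`
#' All terms in one file share a namespace (GMT exports are per-ontology),
#' declared by the caller.
#'
#' @param path GMT file path.
#' @param namespace one of `"BP"`, `"MF"`, `"CC"`, `"KEGG"`.
#' @param background optional explicit background gene vector.
#' @return an `annotation_db`.
#' @export
read_gmt <- function(path, namespace = c("BP", "MF", "CC", "KEGG"),
                     background = NULL) {
  namespace <- match.arg(namespace)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file '", basename(path), "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) stop("GMT line(s) with fewer than three fields: ",
                       paste(which(short), collapse = ", "))
  terms <- data.frame(
    term_id = vapply(parts, `[`, "", 1L),
    term_name = vapply(parts, `[`, "", 2L),
    namespace = namespace,
    stringsAsFactors = FALSE)
  terms$genes <- lapply(parts, function(p) p[-(1:2)])
  annotation_db(terms, background = background)
}

#' Write an annotation database as GMT
#'
#' @param db an `annotation_db`.
#' @param path output path.  Terms of all namespaces are written; use
#'   one db per namespace to mirror per-ontology exports.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  lines <- vapply(seq_len(nrow(db$terms)), function(i) {
    paste(c(db$terms$term_id[i], db$terms$term_name[i],
            db$terms$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
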