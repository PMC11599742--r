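# Atom-selection mini-language. Grammar: conjunctions of clauses joined by
# "and"; clauses are
#   chain <id> | resname <code> | resnum <n> | name <list>
# where <list> is "+"-separated atom names and numeric name ranges such as
# "C12-C21" expand inclusively (C12, C13, ..., C21).

#' Parse a selection expression
#'
#' @param expression selection text, e.g.
#'   `"chain A and resname L2P and resnum 270 and name O2+C2+C3+C12-C21"`.
#' @return A list of class `atom_selection` with elements `chain`, `resname`,
#'   `resnum` (each `NULL` if unconstrained) and `names` (expanded character
#'   vector or `NULL`).
#' @export
parse_selection <- function(expression) {
  stopifnot(is_string(expression))
  clauses <- strsplit(expression, "\\s+and\\s+")[[1L]]
  sel <- list(chain = NULL, resname = NULL, resnum = NULL, names = NULL)
  pos <- 1L
  for (cl in clauses) {
    cl <- trimws(cl)
    toks <- strsplit(cl, "\\s+")[[1L]]
    if (length(toks) != 2L) {
      stop2("parse_error",
            "cannot parse clause '%s' at position %d: expected '<keyword> <value>'",
            cl, pos)
    }
    kw <- toks[1L]; val <- toks[2L]
    switch(kw,
      chain = { sel$chain <- c(sel$chain, val) },
      resname = { sel$resname <- c(sel$resname, toupper(val)) },
      resnum = {
        n <- suppressWarnings(as.integer(val))
        if (is.na(n)) stop2("parse_error",
                            "non-integer residue number '%s' at position %d",
                            val, pos)
        sel$resnum <- c(sel$resnum, n)
      },
      name = { sel$names <- c(sel$names, expand_name_list(val, pos)) },
      stop2("parse_error", "unknown keyword '%s' at position %d", kw, pos)
    )
    pos <- pos + nchar(cl) + 5L  # + " and "
  }
  structure(sel, class = "atom_selection")
}

# Expand a "+"-separated name list with inclusive numeric ranges.
expand_name_list <- function(text, pos = 1L) {
  items <- strsplit(text, "+", fixed = TRUE)[[1L]]
  out <- character(0)
  for (it in items) {
    if (!nzchar(it)) {
      stop2("parse_error", "empty name in list '%s' at position %d", text, pos)
    }
    m <- regmatches(it, regexec("^([A-Za-z']+)([0-9]+)-([A-Za-z']*)([0-9]+)$", it))[[1L]]
    if (length(m)) {
      pre1 <- m[2L]; from <- as.integer(m[3L])
      pre2 <- m[4L]; to <- as.integer(m[5L])
      if (nzchar(pre2) && pre2 != pre1) {
        stop2("parse_error",
              "range '%s' mixes prefixes '%s' and '%s'", it, pre1, pre2)
      }
      if (to < from) {
        stop2("parse_error", "descending name range '%s'", it)
      }
      out <- c(out, paste0(pre1, seq.int(from, to)))
    } else {
      out <- c(out, toupper(it))
    }
  }
  out
}

#' Select atoms from a structure
#'
#' Applies a selection expression (see [parse_selection()]) to a structure
#' and returns the matching atom table. An empty result is legal but emits an
#' `empty_selection` warning.
#'
#' @param structure an `mr_structure`.
#' @param expression selection text or a parsed `atom_selection`.
#' @return Atom table of matching atoms, with the expanded requested atom
#'   names in attribute `"requested_names"` when a `name` clause is present.
#' @examples
#' \dontrun{
#' sel <- select_atoms(s, "chain A and resname L2P and resnum 270")
#' }
#' @export
select_atoms <- function(structure, expression) {
  sel <- if (inherits(expression, "atom_selection")) expression
         else parse_selection(expression)
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resname)) keep <- keep & a$resname %in% sel$resname
  if (!is.null(sel$resnum)) keep <- keep & a$resno %in% sel$resnum
  if (!is.null(sel$names)) keep <- keep & toupper(a$atom) %in% sel$names
  out <- a[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warn2("empty_selection", "selection matched no atoms")
  }
  if (!is.null(sel$names)) attr(out, "requested_names") <- sel$names
  out
}
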