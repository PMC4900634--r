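#' Atom selection language
#'
#' A small deterministic selection language over the atom table. The grammar
#' supports `and`, `or`, `not`, parentheses, and the keys:
#'
#' * `name <v>...` — atom name
#' * `resname <v>...` — residue name
#' * `resnum <n|a:b>...` — per-monomer (canonical) residue number; for a
#'   protein atom in monomer m this matches `residue_number - offset*m`, so
#'   `resnum 106` picks the lysine-ring residue in every monomer
#' * `resid <n|a:b>...` — the raw (offset) residue number as stored
#' * `monomer <n>...` — 0-based monomer index (-1 for non-protein)
#' * `element <v>...` — element symbol
#'
#' A key may be followed by several values (union) and numeric keys accept
#' ranges written `a:b`. Resolution is deterministic and returns sorted,
#' unique 1-based atom indices; an empty result is allowed.
#'
#' @param structure A [pk_structure()].
#' @param expression Selection expression string.
#' @return A `pk_selection`: list with `expression` and sorted `indices`.
#' @export
#' @examples
#' st <- build_pentamer(channel_spec(residues_per_monomer = 10,
#'   helices = list(TM1 = 2:8), lysine_ring_resnum = 6, asn_resnum = 4))
#' length(select_atoms(st, "resnum 6 and name CA")$indices)
select_atoms <- function(structure, expression) {
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- sel_parse_or(st, structure)
  if (st$pos <= length(st$toks)) {
    abort(sprintf("selection syntax error: unexpected token '%s'", st$toks[st$pos]))
  }
  structure(list(expression = expression,
                 indices = which(mask)),
            class = "pk_selection")
}

#' @export
print.pk_selection <- function(x, ...) {
  cat(sprintf("<selection '%s': %d atoms>\n", x$expression, length(x$indices)))
  invisible(x)
}

#' Resolve a selection argument to atom indices
#'
#' Accepts a `pk_selection`, an expression string, or a bare integer index
#' vector; returns sorted unique 1-based indices, validated against the
#' structure.
#'
#' @param structure A [pk_structure()].
#' @param sel Selection object, expression string, or integer indices.
#' @param allow_empty If `FALSE`, an empty selection is an error.
#' @return Integer vector of atom indices.
#' @export
resolve_selection <- function(structure, sel, allow_empty = TRUE) {
  idx <- if (inherits(sel, "pk_selection")) {
    sel$indices
  } else if (is.character(sel) && length(sel) == 1L) {
    select_atoms(structure, sel)$indices
  } else if (is.numeric(sel)) {
    sort(unique(as.integer(sel)))
  } else {
    abort("selection must be a pk_selection, an expression string, or indices")
  }
  if (length(idx) > 0L && (min(idx) < 1L || max(idx) > nrow(structure))) {
    abort("selection indices out of range")
  }
  if (!allow_empty && length(idx) == 0L) abort("selection is empty")
  idx
}

sel_tokenize <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L || is.na(expression)) {
    abort("selection expression must be a single string")
  }
  expr <- gsub("\\(", " ( ", expression)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

sel_advance <- function(st) {
  tok <- sel_peek(st)
  st$pos <- st$pos + 1L
  tok
}

sel_parse_or <- function(st, structure) {
  mask <- sel_parse_and(st, structure)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "or") {
    sel_advance(st)
    mask <- mask | sel_parse_and(st, structure)
  }
  mask
}

sel_parse_and <- function(st, structure) {
  mask <- sel_parse_factor(st, structure)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "and") {
    sel_advance(st)
    mask <- mask & sel_parse_factor(st, structure)
  }
  mask
}

sel_keys <- c("name", "resname", "resnum", "resid", "monomer", "element")

sel_parse_factor <- function(st, structure) {
  tok <- sel_peek(st)
  if (is.na(tok)) abort("selection syntax error: unexpected end of expression")
  if (tolower(tok) == "not") {
    sel_advance(st)
    return(!sel_parse_factor(st, structure))
  }
  if (tok == "(") {
    sel_advance(st)
    mask <- sel_parse_or(st, structure)
    if (is.na(sel_peek(st)) || sel_peek(st) != ")") {
      abort("selection syntax error: missing ')'")
    }
    sel_advance(st)
    return(mask)
  }
  if (tolower(tok) %in% sel_keys) {
    return(sel_parse_primary(st, structure))
  }
  abort(sprintf("selection syntax error: unexpected token '%s'", tok))
}

sel_parse_primary <- function(st, structure) {
  key <- tolower(sel_advance(st))
  vals <- character(0)
  stops <- c("and", "or", "not", "(", ")")
  while (!is.na(sel_peek(st)) && !(tolower(sel_peek(st)) %in% stops)) {
    vals <- c(vals, sel_advance(st))
  }
  if (length(vals) == 0L) {
    abort(sprintf("selection syntax error: key '%s' needs at least one value", key))
  }
  field <- switch(key,
    name = structure$atom_name,
    resname = structure$residue_name,
    element = structure$element,
    monomer = structure$monomer_index,
    resid = structure$residue_number,
    resnum = sel_canonical_resnum(structure)
  )
  if (key %in% c("resnum", "resid", "monomer")) {
    nums <- sel_expand_numeric(vals, key)
    field %in% nums
  } else {
    field %in% vals
  }
}

sel_canonical_resnum <- function(structure) {
  off <- monomer_offset(structure)
  m <- structure$monomer_index
  ifelse(m >= 0L, structure$residue_number - off * m, structure$residue_number)
}

sel_expand_numeric <- function(vals, key) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
      ab <- as.integer(strsplit(v, ":")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      abort(sprintf("selection syntax error: '%s' is not a number or range for key '%s'",
                    v, key))
    }
  }
  out
}
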