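#' Resolve an atom selection expression
#'
#' A small selection mini-language for naming atom sets, e.g. the
#' active-site definition "all protein residues with at least one atom
#' within 4 Angstrom of the lesion".  Terms:
#'
#' * `chain A B` - by chain identifier
#' * `resname HOH 8OG` - by residue name
#' * `resnum 1-14 20` - by residue number (ranges allowed; an empty range
#'   such as `1-0` selects nothing)
#' * `name CA C1'` - by atom name
#' * `elem O N` - by element
#' * `protein` / `dna` / `water` / `ion` / `other` - by residue class
#' * `all`, `none`
#' * `within 4.0 of <expr>` - atoms within the given distance (Angstrom)
#'   of any atom matched by `<expr>`; requires `context_snapshot`
#' * `byres <expr>` - expand to whole residues containing a match
#' * `not`, `and`, `or`, parentheses; `and` binds tighter than `or`
#'
#' @param topology A `topology`.
#' @param expression Selection string.
#' @param context_snapshot Optional `n_atoms x 3` coordinate matrix,
#'   required by `within` terms.
#' @return Sorted integer vector of atom indices (possibly empty).
#' @examples
#' ## within the toy complex: all lesion-strand phosphorus atoms
#' ## resolve_selection(top, "dna and elem P")
#' @export
resolve_selection <- function(topology, expression, context_snapshot = NULL) {
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  st$top <- topology
  st$coords <- context_snapshot
  st$expr <- expression
  res <- sel_parse_or(st)
  if (st$pos <= length(st$toks))
    stop(sprintf("selection syntax error at token %d ('%s') in \"%s\"",
                 st$pos, st$toks[st$pos], expression))
  sort(which(res))
}

sel_tokenize <- function(expression) {
  s <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(s), "[ \t]+")[[1]]
  toks[nzchar(toks)]
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
sel_next <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }
sel_err <- function(st, msg) {
  stop(sprintf("selection syntax error at token %d in \"%s\": %s", st$pos, st$expr, msg))
}

sel_parse_or <- function(st) {
  res <- sel_parse_and(st)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "or") {
    sel_next(st)
    res <- res | sel_parse_and(st)
  }
  res
}

sel_parse_and <- function(st) {
  res <- sel_parse_unary(st)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "and") {
    sel_next(st)
    res <- res & sel_parse_unary(st)
  }
  res
}

sel_parse_unary <- function(st) {
  t <- sel_peek(st)
  if (is.na(t)) sel_err(st, "unexpected end of expression")
  lt <- tolower(t)
  if (lt == "not") {
    sel_next(st)
    return(!sel_parse_unary(st))
  }
  if (lt == "within") {
    sel_next(st)
    d <- suppressWarnings(as.numeric(sel_next(st)))
    if (!is.finite(d)) sel_err(st, "'within' needs a numeric distance")
    if (tolower(sel_next(st)) != "of") sel_err(st, "'within <R> of <expr>' expected")
    inner <- sel_parse_unary(st)
    if (is.null(st$coords))
      stop("selection uses 'within' but no context snapshot was supplied")
    ref <- st$coords[inner, , drop = FALSE]
    if (nrow(ref) == 0) return(rep(FALSE, n_atoms(st$top)))
    ok <- min_dist_to_set(st$coords, ref) <= d
    return(ok)
  }
  if (lt == "byres") {
    sel_next(st)
    inner <- sel_parse_unary(st)
    ri <- unique(st$top$atoms$res_index[inner])
    return(st$top$atoms$res_index %in% ri)
  }
  if (t == "(") {
    sel_next(st)
    res <- sel_parse_or(st)
    if (!identical(sel_next(st), ")")) sel_err(st, "missing ')'")
    return(res)
  }
  sel_parse_term(st)
}

SEL_KEYWORDS <- c("and", "or", "not", "within", "of", "byres", "(", ")")

sel_take_values <- function(st) {
  vals <- character(0)
  repeat {
    t <- sel_peek(st)
    if (is.na(t) || tolower(t) %in% SEL_KEYWORDS) break
    vals <- c(vals, sel_next(st))
  }
  if (length(vals) == 0) sel_err(st, "term needs at least one value")
  vals
}

sel_parse_term <- function(st) {
  top <- st$top
  a <- top$atoms
  t <- tolower(sel_next(st))
  switch(t,
    "all" = rep(TRUE, nrow(a)),
    "none" = rep(FALSE, nrow(a)),
    "protein" = , "dna" = , "water" = , "ion" = , "other" = {
      cls <- top$residues$class[match(a$res_index, top$residues$res_index)]
      cls == t
    },
    "chain" = a$chain %in% sel_take_values(st),
    "resname" = a$resname %in% sel_take_values(st),
    "name" = a$name %in% sel_take_values(st),
    "elem" = toupper(a$elem) %in% toupper(sel_take_values(st)),
    "resnum" = {
      vals <- sel_take_values(st)
      keep <- integer(0)
      for (v in vals) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
          m <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
          lo <- as.integer(m[2]); hi <- as.integer(m[3])
          if (lo <= hi) keep <- c(keep, lo:hi)
        } else if (grepl("^-?[0-9]+$", v)) {
          keep <- c(keep, as.integer(v))
        } else sel_err(st, paste0("bad residue number '", v, "'"))
      }
      a$resnum %in% keep
    },
    sel_err(st, paste0("unknown term '", t, "'"))
  )
}

# minimum distance from every atom to a reference coordinate set,
# blockwise to bound memory
min_dist_to_set <- function(coords, ref) {
  n <- nrow(coords)
  out <- numeric(n)
  step <- max(1L, floor(2e6 / nrow(ref)))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + step - 1L)
    blk <- coords[i:j, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(ref^2), "+") - 2 * blk %*% t(ref)
    out[i:j] <- sqrt(pmax(0, apply(d2, 1, min)))
    i <- j + 1L
  }
  out
}
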