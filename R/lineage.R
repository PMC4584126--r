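#' @importFrom rlang %||% .data abort warn
#' @importFrom stats median quantile cor setNames
#' @importFrom utils head tail
NULL

# Canonical rank ladder, kingdom down to species. A lineage is a prefix of
# this ladder: gaps are only allowed at the tail.
RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

GG_PREFIX <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
               f = "family", g = "genus", s = "species")

#' Construct a lineage
#'
#' A lineage is an ordered set of rank:name pairs starting at kingdom, with
#' no internal gaps: internally it is a named character vector whose names
#' are a prefix of `kingdom, phylum, class, order, family, genus, species`.
#'
#' @param names Character vector of taxon names, ordered from kingdom down.
#' @param ranks Character vector of ranks, same length as `names`. Defaults
#'   to the first `length(names)` canonical ranks.
#' @return An object of class `lineage` (possibly empty).
#' @export
#' @examples
#' new_lineage(c("Bacteria", "Firmicutes"))
new_lineage <- function(names = character(), ranks = RANKS[seq_along(names)]) {
  stopifnot(length(names) == length(ranks))
  if (length(ranks) > 0 && !identical(unname(ranks), RANKS[seq_along(ranks)])) {
    abort("lineage ranks must be the canonical prefix kingdom..species",
          class = "panfun_lineage_error")
  }
  structure(setNames(as.character(names), ranks), class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  if (length(x) == 0) cat("<empty lineage>\n")
  else cat(lineage_string(x), "\n")
  invisible(x)
}

#' @export
format.lineage <- function(x, ...) lineage_string(x)

is_lineage <- function(x) inherits(x, "lineage")

#' Canonical string form of a lineage
#'
#' Renders a lineage in the `rank:Name; rank:Name` dialect used by the
#' reference-database files and the run logs.
#'
#' @param lin A `lineage`.
#' @return A single string; `""` for an empty lineage.
#' @export
lineage_string <- function(lin) {
  if (length(lin) == 0) return("")
  paste(paste0(names(lin), ":", unname(lin)), collapse = "; ")
}

#' Depth, lowest rank and lowest name of a lineage
#'
#' @param lin A `lineage`.
#' @return `lineage_depth()` the number of resolved ranks; `lowest_rank()` /
#'   `lowest_name()` the rank / taxon name of the deepest resolved level
#'   (`NA` for an empty lineage).
#' @export
lineage_depth <- function(lin) length(lin)

#' @rdname lineage_depth
#' @export
lowest_rank <- function(lin) {
  if (length(lin) == 0) return(NA_character_)
  names(lin)[length(lin)]
}

#' @rdname lineage_depth
#' @export
lowest_name <- function(lin) {
  if (length(lin) == 0) return(NA_character_)
  unname(lin[length(lin)])
}

# normalized matching key for a taxon name: whitespace-squished, case-folded
norm_name <- function(x) stringr::str_squish(tolower(x))

# key for a (rank, name) pair; used by the genome index and taxonomy lookups
rank_key <- function(rank, name) paste(rank, norm_name(name), sep = "\r")

lineage_keys <- function(lin) {
  if (length(lin) == 0) return(character())
  rank_key(names(lin), unname(lin))
}

#' Parse taxonomy strings into lineages
#'
#' Understands the three dialects commonly found in QIIME-style OTU tables:
#' Greengenes prefixes (`k__Bacteria; p__Firmicutes; ...`), explicit
#' rank-colon pairs (`kingdom:Bacteria; phylum:Firmicutes; ...`), and bare
#' semicolon-separated names interpreted positionally from kingdom down.
#' Prefixes and surrounding whitespace are stripped. An empty field (`g__`,
#' a trailing `;`, or a skipped rank in the rank-colon dialect) terminates
#' the lineage at the last non-empty rank above it.
#'
#' @param x Character vector of raw taxonomy strings.
#' @param dialect One of `"auto"`, `"greengenes_prefix"`, `"rank_colon"`,
#'   `"bare_semicolon"`. `"auto"` detects per string: >= 50% of fields with
#'   an `x__` prefix selects Greengenes; otherwise any `rank:` field selects
#'   rank-colon; otherwise bare.
#' @param otu_ids Optional ids used in error messages.
#' @return A list of `lineage` objects, one per element of `x`. A fully
#'   empty taxonomy yields an empty lineage (callers decide to drop it).
#' @export
#' @examples
#' parse_lineage("k__Bacteria; p__Firmicutes; c__Bacilli")[[1]]
parse_lineage <- function(x, dialect = c("auto", "greengenes_prefix",
                                         "rank_colon", "bare_semicolon"),
                          otu_ids = NULL) {
  dialect <- match.arg(dialect)
  purrr::map(seq_along(x), function(i) {
    parse_lineage_one(x[[i]], dialect,
                      id = if (is.null(otu_ids)) i else otu_ids[[i]])
  })
}

detect_dialect <- function(fields) {
  if (length(fields) == 0) return("bare_semicolon")
  n_gg <- sum(stringr::str_detect(fields, "^[a-z]__"))
  if (n_gg / length(fields) >= 0.5) return("greengenes_prefix")
  rank_rx <- paste0("^(", paste(RANKS, collapse = "|"), "):")
  if (any(stringr::str_detect(fields, rank_rx))) return("rank_colon")
  "bare_semicolon"
}

parse_lineage_one <- function(raw, dialect, id = "?") {
  if (is.na(raw) || stringr::str_squish(raw) == "") return(new_lineage())
  fields <- stringr::str_trim(strsplit(raw, ";", fixed = TRUE)[[1]])
  # drop a trailing run of empty fields produced by "...; "
  while (length(fields) > 0 && fields[length(fields)] == "")
    fields <- fields[-length(fields)]
  if (length(fields) == 0) return(new_lineage())
  if (dialect == "auto") dialect <- detect_dialect(fields)

  if (dialect == "greengenes_prefix") {
    m <- stringr::str_match(fields, "^([a-z])__\\s*(.*)$")
    bad <- is.na(m[, 1]) | !m[, 2] %in% names(GG_PREFIX)
    if (all(bad)) {
      abort(paste0("OTU '", id, "': no recognizable 'x__' fields in taxonomy: ",
                   raw), class = "panfun_parse_error")
    }
    ranks <- GG_PREFIX[m[, 2]]
    names_ <- stringr::str_squish(m[, 3])
    names_[bad] <- ""
    ranks[bad] <- NA_character_
    return(assemble_lineage(ranks, names_))
  }

  if (dialect == "rank_colon") {
    m <- stringr::str_match(fields, "^([A-Za-z]+)\\s*:\\s*(.*)$")
    ranks <- tolower(m[, 2])
    ranks[!ranks %in% RANKS] <- NA_character_
    names_ <- stringr::str_squish(m[, 3])
    names_[is.na(m[, 1])] <- ""
    if (all(is.na(ranks))) {
      abort(paste0("OTU '", id, "': no recognizable 'rank:' fields in taxonomy: ",
                   raw), class = "panfun_parse_error")
    }
    return(assemble_lineage(ranks, names_))
  }

  # bare_semicolon: positional from kingdom down
  names_ <- stringr::str_squish(fields)
  n <- min(length(names_), length(RANKS))
  assemble_lineage(RANKS[seq_len(n)], names_[seq_len(n)])
}

# Walk the canonical ladder; stop at the first rank that is missing, out of
# order, repeated, or empty — everything below an internal gap is dropped.
assemble_lineage <- function(ranks, names_) {
  out <- character()
  for (r in RANKS) {
    j <- which(!is.na(ranks) & ranks == r)
    if (length(j) == 0) break
    nm <- names_[j[1]]
    if (is.na(nm) || nm == "") break
    out[r] <- nm
  }
  new_lineage(unname(out), names(out))
}

#' Truncate a lineage at a given rank
#'
#' @param lin A `lineage`.
#' @param rank Rank to keep down to (inclusive).
#' @return The truncated `lineage`.
#' @keywords internal
lineage_prefix <- function(lin, rank) {
  k <- match(rank, RANKS)
  keep <- names(lin)[match(names(lin), RANKS) <= k]
  new_lineage(unname(lin[keep]), keep)
}

#' Convert lineages to a tidy tibble
#'
#' @param x A list of `lineage` objects (or a single one).
#' @param ids Optional id column values.
#' @return A tibble with columns `id`, `rank`, `name`, one row per resolved
#'   rank.
#' @export
lineage_tibble <- function(x, ids = NULL) {
  if (is_lineage(x)) x <- list(x)
  ids <- ids %||% seq_along(x)
  purrr::map2_dfr(x, ids, function(lin, id) {
    if (length(lin) == 0) {
      return(tibble::tibble(id = id, rank = character(), name = character()))
    }
    tibble::tibble(id = id, rank = names(lin), name = unname(lin))
  })
}
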