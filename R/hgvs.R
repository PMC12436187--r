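# HGVS protein-change parsing for the variant classes occurring in FOXG1
# syndrome cohorts: missense substitutions, nonsense (premature stop) and
# frameshift changes. Both three-letter ("p.Gln86AspfsTer34") and compact
# one-letter ("Q86Dfs*34", "E136X") notations are accepted; the canonical
# internal form is the compact one-letter style.

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Ter = "*"
)

.aa1 <- function(token) {
  if (token %in% c("Ter", "X", "*")) return("*")
  if (nchar(token) == 3) {
    out <- unname(AA_THREE_TO_ONE[token])
    if (is.na(out)) {
      stop("unrecognized amino-acid token '", token, "'", call. = FALSE)
    }
    return(out)
  }
  if (nchar(token) == 1 && token %in% AA_THREE_TO_ONE) return(token)
  stop("unrecognized amino-acid token '", token, "'", call. = FALSE)
}

#' Parse an HGVS protein change
#'
#' Parses missense, nonsense and frameshift protein changes in either
#' three-letter HGVS form (with or without the `p.` prefix) or compact
#' one-letter form. Both notations of the same change parse to identical
#' records.
#'
#' @param p_string A protein-change string, e.g. `"p.Gln86AspfsTer34"`,
#'   `"Q86Dfs*34"`, `"E136X"`, `"p.Tyr416Ter"`, `"P182Q"`.
#'
#' @return An object of class `hgvs_protein_change`: a list with elements
#'   `ref` (one-letter reference residue), `position` (integer, first altered
#'   residue), `alt` (one-letter alternate residue, `"*"` for a stop),
#'   `fs_ter_offset` (integer position of the new stop downstream of the
#'   frameshift, `NA` for non-frameshift changes) and `canonical` (compact
#'   one-letter label, stop written `X` for nonsense changes).
#'
#' @examples
#' parse_hgvs_protein("p.Gln86AspfsTer34")
#' parse_hgvs_protein("E136X")
#' identical(parse_hgvs_protein("p.Tyr416Ter"), parse_hgvs_protein("Y416X"))
#' @export
parse_hgvs_protein <- function(p_string) {
  if (!is.character(p_string) || length(p_string) != 1 || is.na(p_string) ||
      !nzchar(p_string)) {
    stop("p_string must be a single non-empty string", call. = FALSE)
  }
  s <- gsub("^p\\.", "", trimws(p_string))
  s <- gsub("[()]", "", s)

  aa3 <- "[A-Z][a-z]{2}"
  patterns <- list(
    # three-letter frameshift: Gln86AspfsTer34
    fs3 = paste0("^(", aa3, ")(\\d+)(", aa3, ")fs(?:Ter|\\*)(\\d+)$"),
    # one-letter frameshift: Q86Dfs*34 (also Q86DfsTer34)
    fs1 = "^([A-Z])(\\d+)([A-Z])fs(?:Ter|\\*)(\\d+)$",
    # three-letter nonsense: Glu136Ter
    non3 = paste0("^(", aa3, ")(\\d+)(?:Ter|\\*)$"),
    # one-letter nonsense: E136X or E136*
    non1 = "^([A-Z])(\\d+)(?:X|\\*)$",
    # three-letter missense: Pro182Gln
    mis3 = paste0("^(", aa3, ")(\\d+)(", aa3, ")$"),
    # one-letter missense: P182Q
    mis1 = "^([A-Z])(\\d+)([A-Z])$"
  )

  for (kind in names(patterns)) {
    m <- regmatches(s, regexec(patterns[[kind]], s))[[1]]
    if (length(m) == 0) next
    ref <- .aa1(m[2])
    pos <- suppressWarnings(as.integer(m[3]))
    if (is.na(pos) || pos < 1) {
      stop("invalid residue position '", m[3], "' in '", p_string, "'",
           call. = FALSE)
    }
    if (kind %in% c("fs3", "fs1")) {
      alt <- .aa1(m[4])
      off <- as.integer(m[5])
      if (off < 1) {
        stop("invalid frameshift stop offset in '", p_string, "'",
             call. = FALSE)
      }
      canonical <- sprintf("%s%d%sfs*%d", ref, pos, alt, off)
      change <- list(ref = ref, position = pos, alt = alt,
                     fs_ter_offset = off, canonical = canonical)
    } else if (kind %in% c("non3", "non1")) {
      canonical <- sprintf("%s%dX", ref, pos)
      change <- list(ref = ref, position = pos, alt = "*",
                     fs_ter_offset = NA_integer_, canonical = canonical)
    } else {
      alt <- .aa1(m[4])
      if (alt == ref) {
        stop("synonymous change '", p_string, "' is not supported",
             call. = FALSE)
      }
      canonical <- sprintf("%s%d%s", ref, pos, alt)
      change <- list(ref = ref, position = pos, alt = alt,
                     fs_ter_offset = NA_integer_, canonical = canonical)
    }
    class(change) <- "hgvs_protein_change"
    return(change)
  }
  stop("cannot parse protein change '", p_string,
       "': expected missense (P182Q), nonsense (E136X/p.Glu136Ter) or ",
       "frameshift (Q86Dfs*34/p.Gln86AspfsTer34) notation", call. = FALSE)
}

#' @export
print.hgvs_protein_change <- function(x, ...) {
  cat("<hgvs_protein_change>", x$canonical, "\n")
  invisible(x)
}

#' Classify the coding effect of a parsed protein change
#'
#' @param change An `hgvs_protein_change` from [parse_hgvs_protein()].
#' @return One of `"missense"`, `"nonsense"`, `"frameshift"`.
#' @examples
#' classify_coding_effect(parse_hgvs_protein("E136X"))
#' @export
classify_coding_effect <- function(change) {
  stopifnot(inherits(change, "hgvs_protein_change"))
  if (!is.na(change$fs_ter_offset)) return("frameshift")
  if (identical(change$alt, "*")) return("nonsense")
  if (change$alt %in% AA_THREE_TO_ONE && change$alt != change$ref) {
    return("missense")
  }
  stop("unsupported coding effect for change '", change$canonical, "'",
       call. = FALSE)
}
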