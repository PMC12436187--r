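# FOXG1 protein-domain map. The forkhead DNA-binding domain (FBD) and its
# adjacent conserved segment (CS) sit in the middle of the 489-aa human
# protein; published cohort tables assign variants to N-terminal, "FBD, CS",
# FBD, or C-terminal regions. Exact interval boundaries are configurable;
# the default map is the minimal contiguous tiling consistent with the
# packaged cohort's domain column.

DOMAIN_LEVELS <- c("N_terminal", "FBD_CS", "FBD", "C_terminal")

#' Construct a FOXG1 domain map
#'
#' A domain map is an ordered set of non-overlapping, contiguous amino-acid
#' intervals covering positions 1..`protein_length`. The default places the
#' FBD/CS region at residues 182–194, the FBD proper at 195–306 and the
#' C-terminal region from residue 307, consistent with the packaged cohort's
#' domain assignments (human FOXG1, 489 aa).
#'
#' @param intervals A data.frame with columns `name`, `start`, `end`
#'   (1-based, inclusive). Defaults to the map described above.
#' @param protein_length Total protein length the map must cover.
#' @return A `domain_map` object (validated data.frame).
#' @examples
#' m <- foxg1_domain_map()
#' assign_domain(230, m)
#' @export
foxg1_domain_map <- function(intervals = NULL, protein_length = 489L) {
  if (is.null(intervals)) {
    intervals <- data.frame(
      name  = DOMAIN_LEVELS,
      start = c(1L, 182L, 195L, 307L),
      end   = c(181L, 194L, 306L, protein_length),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(intervals),
            all(c("name", "start", "end") %in% names(intervals)))
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  if (nrow(intervals) < 1 || anyNA(intervals$start) || anyNA(intervals$end)) {
    stop("domain map intervals must have integer start/end", call. = FALSE)
  }
  if (intervals$start[1] != 1L) {
    stop("domain map must start at residue 1", call. = FALSE)
  }
  if (intervals$end[nrow(intervals)] != protein_length) {
    stop("domain map must end at the protein length (", protein_length, ")",
         call. = FALSE)
  }
  if (any(intervals$end < intervals$start)) {
    stop("domain map intervals must have start <= end", call. = FALSE)
  }
  if (nrow(intervals) > 1) {
    gaps <- intervals$start[-1] - intervals$end[-nrow(intervals)]
    if (any(gaps != 1L)) {
      stop("domain map intervals must be ascending and contiguous",
           call. = FALSE)
    }
  }
  attr(intervals, "protein_length") <- as.integer(protein_length)
  class(intervals) <- c("domain_map", "data.frame")
  intervals
}

#' Assign the domain of an amino-acid position
#'
#' Truncating (nonsense/frameshift) variants are assigned by the position of
#' the first altered residue, not by the span of lost sequence.
#'
#' @param position Integer amino-acid index (first altered residue).
#' @param domain_map A [foxg1_domain_map()].
#' @return The domain name at `position`.
#' @export
assign_domain <- function(position, domain_map = foxg1_domain_map()) {
  stopifnot(inherits(domain_map, "domain_map"))
  position <- as.integer(position)
  len <- attr(domain_map, "protein_length")
  if (length(position) != 1 || is.na(position) || position < 1 ||
      position > len) {
    stop("position must be a single integer in [1, ", len, "]", call. = FALSE)
  }
  hit <- domain_map$start <= position & position <= domain_map$end
  domain_map$name[which(hit)[1]]
}
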