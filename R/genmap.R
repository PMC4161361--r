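#' Construct a genetic map
#'
#' A genetic map is an ordered set of chromosomes, each carrying named
#' markers at strictly increasing positions in centimorgans (cM).
#'
#' @param marker Character vector of marker names (unique).
#' @param chrom Chromosome identifier per marker (character or factor);
#'   chromosome order is the order of first appearance.
#' @param pos_cM Numeric marker positions in cM, chromosome-local.
#' @return An object of class `"genmap"`: a data frame with columns
#'   `marker`, `chrom`, `pos_cM`, sorted chromosome-major then by position,
#'   with attribute `chrom_len` (named vector of chromosome spans in cM).
#' @examples
#' gm <- genetic_map(paste0("m", 1:4), c(1, 1, 2, 2), c(0, 50, 0, 80))
#' chrom_lengths(gm)
#' @export
genetic_map <- function(marker, chrom, pos_cM) {
  marker <- as.character(marker)
  chrom <- rep(as.character(chrom), length.out = length(marker))
  pos_cM <- as.numeric(pos_cM)
  if (length(marker) != length(pos_cM))
    stop("marker and pos_cM must have equal length")
  if (anyDuplicated(marker)) stop("duplicate marker names: ",
                                  paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(!is.finite(pos_cM)) || any(pos_cM < 0))
    stop("marker positions must be finite and >= 0")
  chrom_levels <- unique(chrom)
  ord <- order(match(chrom, chrom_levels), pos_cM)
  m <- data.frame(marker = marker[ord], chrom = chrom[ord], pos_cM = pos_cM[ord],
                  stringsAsFactors = FALSE)
  for (ch in chrom_levels) {
    p <- m$pos_cM[m$chrom == ch]
    if (length(p) < 2) stop("chromosome ", ch, " has fewer than 2 markers")
    if (any(diff(p) <= 0)) stop("marker positions on chromosome ", ch,
                                " are not strictly increasing")
  }
  attr(m, "chrom_len") <- vapply(chrom_levels,
                                 function(ch) max(m$pos_cM[m$chrom == ch]),
                                 numeric(1))
  class(m) <- c("genmap", "data.frame")
  m
}

#' @export
print.genmap <- function(x, ...) {
  len <- attr(x, "chrom_len")
  cat("Genetic map:", length(len), "chromosomes,", nrow(x), "markers\n")
  for (ch in names(len)) {
    n <- sum(x$chrom == ch)
    cat(sprintf("  %s: %d markers, %.1f cM\n", ch, n, len[[ch]]))
  }
  invisible(x)
}

#' Chromosome lengths of a genetic map
#' @param map A `"genmap"` object.
#' @return Named numeric vector of chromosome spans (position of last marker).
#' @export
chrom_lengths <- function(map) {
  stopifnot(inherits(map, "genmap"))
  attr(map, "chrom_len")
}

#' Read a genetic map from CSV
#'
#' Expects a header with columns `marker`, `chrom`, `pos_cM` (any order,
#' extra columns ignored); rows may be unsorted.
#' @param path Path to the CSV file.
#' @return A `"genmap"` object.
#' @export
read_map_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos_cM")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("map CSV ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  genetic_map(df$marker, df$chrom, df$pos_cM)
}

#' Write a genetic map to CSV
#' @param map A `"genmap"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "genmap"))
  utils::write.csv(as.data.frame(map)[c("marker", "chrom", "pos_cM")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map distance to recombination fraction (Haldane)
#'
#' Haldane's map function r = (1 - exp(-2 d)) / 2 with d in Morgans,
#' assuming no crossover interference; the inverse of [recomb_to_map_distance()].
#'
#' @param d_cM Non-negative map distance(s) in centimorgans.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Recombination fraction(s) in \[0, 0.5).
#' @examples
#' map_distance_to_recomb(50)   # 0.3160603
#' @export
map_distance_to_recomb <- function(d_cM, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(!is.finite(d_cM)) || any(d_cM < 0))
    stop("map distance must be finite and non-negative")
  d <- d_cM / 100
  switch(map_function,
         haldane = 0.5 * (1 - exp(-2 * d)),
         kosambi = 0.5 * tanh(2 * d))
}

#' Recombination fraction to map distance (inverse Haldane)
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @param map_function `"haldane"` or `"kosambi"`.
#' @return Map distance(s) in cM.
#' @export
recomb_to_map_distance <- function(r, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  100 * switch(map_function,
               haldane = -0.5 * log(1 - 2 * r),
               kosambi = 0.25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' Build the genome-wide grid of putative loci
#'
#' Putative QTL positions at which genotype indicators are evaluated: every
#' marker position plus interior points at multiples of `step_cM` from the
#' chromosome start, ordered chromosome-major then by position.
#'
#' @param map A `"genmap"` object.
#' @param step_cM Positive grid step in cM (default 1).
#' @return An object of class `"locus_grid"`: a data frame with columns
#'   `chrom`, `pos_cM`, `genome_cM` (cumulative coordinate), `left_marker`,
#'   `right_marker` (row indices into `map`), `at_marker` (logical);
#'   attributes `map` and `step_cM`.
#' @examples
#' gm <- genetic_map(c("a", "b"), c(1, 1), c(0, 10))
#' locus_grid(gm, 5)$pos_cM   # 0 5 10
#' @export
locus_grid <- function(map, step_cM = 1) {
  stopifnot(inherits(map, "genmap"))
  if (!is.finite(step_cM) || step_cM <= 0) stop("step_cM must be > 0")
  len <- chrom_lengths(map)
  out <- vector("list", length(len))
  for (ci in seq_along(len)) {
    ch <- names(len)[ci]
    rows <- which(map$chrom == ch)
    mpos <- map$pos_cM[rows]
    first <- mpos[1]; last <- mpos[length(mpos)]
    steps <- first + seq(0, floor((last - first) / step_cM)) * step_cM
    pos <- sort(unique(c(mpos, steps)))
    # snap grid points numerically indistinguishable from markers onto them
    at <- vapply(pos, function(p) any(abs(mpos - p) < 1e-9), logical(1))
    li <- findInterval(pos + 1e-9, mpos)
    ri <- ifelse(at, li, pmin(li + 1L, length(mpos)))
    out[[ci]] <- data.frame(chrom = ch, pos_cM = pos,
                            genome_cM = pos + cum_offset(map, ch),
                            left_marker = rows[li], right_marker = rows[ri],
                            at_marker = at, stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, out)
  rownames(g) <- NULL
  attr(g, "map") <- map
  attr(g, "step_cM") <- step_cM
  class(g) <- c("locus_grid", "data.frame")
  g
}

#' @export
print.locus_grid <- function(x, ...) {
  cat("Locus grid:", nrow(x), "putative loci on",
      length(unique(x$chrom)), "chromosomes (step",
      attr(x, "step_cM"), "cM)\n")
  invisible(x)
}

# cumulative cM offset of a chromosome's origin (sum of preceding lengths)
cum_offset <- function(map, chrom) {
  len <- chrom_lengths(map)
  idx <- match(chrom, names(len))
  if (is.na(idx)) stop("unknown chromosome: ", chrom)
  if (idx == 1) 0 else sum(len[seq_len(idx - 1)])
}

#' Genome-wide cumulative position
#'
#' Converts a chromosome-local position to a genome-wide coordinate: the
#' local position plus the summed lengths of all preceding chromosomes
#' (e.g. 48 cM on the second 100 cM chromosome is 148).
#'
#' @param map A `"genmap"` object.
#' @param chrom Chromosome name(s).
#' @param pos_cM Chromosome-local position(s) in cM.
#' @return Genome-wide coordinate(s) in cM.
#' @seealso [genome_to_local()] for the inverse.
#' @export
cumulative_position <- function(map, chrom, pos_cM) {
  len <- chrom_lengths(map)
  chrom <- as.character(chrom)
  bad <- !(chrom %in% names(len))
  if (any(bad)) stop("unknown chromosome: ", paste(unique(chrom[bad]), collapse = ", "))
  if (any(pos_cM < 0 | pos_cM > len[chrom]))
    stop("position outside chromosome span")
  offs <- cumsum(c(0, unname(len)))[match(chrom, names(len))]
  offs + pos_cM
}

#' Invert a genome-wide coordinate to (chromosome, local position)
#' @param map A `"genmap"` object.
#' @param genome_cM Genome-wide coordinate(s) in cM.
#' @return Data frame with columns `chrom` and `pos_cM`.
#' @export
genome_to_local <- function(map, genome_cM) {
  len <- chrom_lengths(map)
  ends <- cumsum(unname(len))
  starts <- c(0, ends[-length(ends)])
  if (any(genome_cM < 0 | genome_cM > ends[length(ends)] + 1e-9))
    stop("genome coordinate outside map span")
  # a coordinate on a chromosome boundary maps to the end of the earlier one
  idx <- pmax(pmin(findInterval(genome_cM, starts + 1e-9), length(len)), 1L)
  data.frame(chrom = names(len)[idx], pos_cM = genome_cM - starts[idx],
             stringsAsFactors = FALSE)
}
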