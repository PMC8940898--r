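#' Parse a genomic segment from its text form
#'
#' Text coordinates are 1-based inclusive with optional comma grouping
#' (\code{"chr3:45,859,651-45,909,024"}); the returned \linkS4class{Segment}
#' stores 0-based half-open coordinates, so its length in bp is
#' \code{end - start}.
#'
#' @param text a single string \code{"chr<X>:<start>-<end>"}.
#' @param label optional free-text label attached to the segment.
#' @return a \linkS4class{Segment}.
#' @examples
#' seg <- parseSegment("chr3:45,859,651-45,909,024")
#' formatSegment(seg)
#' @export
parseSegment <- function(text, label = "") {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text,
    regexec("^([A-Za-z0-9_.]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
  if (length(m) != 4L)
    stop("malformed segment text: '", text,
         "' (expected \"chr<X>:<start>-<end>\")")
  start1 <- as.numeric(gsub(",", "", m[3]))
  end1 <- as.numeric(gsub(",", "", m[4]))
  if (start1 < 1) stop("segment start must be >= 1 (1-based inclusive)")
  if (start1 >= end1) stop("empty segment: '", text, "'")
  new("Segment", chrom = m[2], start = start1 - 1, end = end1,
      label = label)
}

#' Serialize a Segment to 1-based inclusive text
#'
#' Inverse of \code{\link{parseSegment}} (without comma grouping), so
#' \code{formatSegment(parseSegment(x))} reproduces \code{x} up to commas.
#'
#' @param segment a \linkS4class{Segment}.
#' @return a string \code{"chr<X>:<start>-<end>"}.
#' @export
formatSegment <- function(segment) {
  stopifnot(is(segment, "Segment"))
  sprintf("%s:%.0f-%.0f", segment@chrom, segment@start + 1, segment@end)
}

#' @export
setMethod("as.character", "Segment", function(x, ...) formatSegment(x))

#' Segment length in base pairs
#' @param segment a \linkS4class{Segment}.
#' @return integer length.
#' @export
segmentLength <- function(segment) {
  as.integer(segment@end - segment@start)
}

#' Symmetrically dilate a segment
#'
#' Extends the segment by \code{bp} base pairs on both sides (clamped at
#' position 0), as used by the dilation experiment.
#'
#' @param segment a \linkS4class{Segment}.
#' @param bp nonnegative extension in bp applied to each side.
#' @return a \linkS4class{Segment}.
#' @export
dilateSegment <- function(segment, bp) {
  stopifnot(bp >= 0)
  new("Segment", chrom = segment@chrom,
      start = max(0, segment@start - bp), end = segment@end + bp,
      label = segment@label)
}

#' Coerce a Segment to GRanges
#' @name Segment-coerce
#' @aliases coerce,Segment,GRanges-method
#' @exportMethod coerce
setAs("Segment", "GRanges", function(from) {
  GenomicRanges::GRanges(from@chrom,
                         IRanges::IRanges(from@start + 1, from@end))
})

# which variant positions (1-based) fall inside a segment
segmentContains <- function(segment, chrom, pos) {
  chrom == segment@chrom & pos >= segment@start + 1 & pos <= segment@end
}
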