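#' Variant key serialization
#'
#' A variant key identifies one (site, alternate allele) pair after
#' multi-allelic decomposition, serialized as `"chrom:pos_ref/alt"`
#' (e.g. `"chr2:21232683_G/A"`). Positions are 1-based VCF coordinates.
#'
#' @param chrom chromosome label(s)
#' @param pos 1-based position(s)
#' @param ref,alt reference / alternate allele strings
#' @return `variant_key()` returns a character vector of keys;
#'   `parse_variant_key()` returns a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' variant_key("chr2", 21232683, "G", "A")
#' parse_variant_key("chr2:21232683_G/A")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  stopifnot(all(pos >= 1), all(ref != alt))
  sprintf("%s:%d_%s/%s", chrom, as.integer(pos), ref, alt)
}

#' @param key character vector of serialized keys
#' @rdname variant_key
#' @export
parse_variant_key <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):([0-9]+)_([ACGTN]+)/([ACGTN]+)$", key))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("malformed variant key: ", paste(key[bad], collapse = ", "))
  }
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    pos = as.integer(vapply(m, `[`, "", 3L)),
    ref = vapply(m, `[`, "", 4L),
    alt = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}
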