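#' Built-in genome descriptions
#'
#' `yeast_genome()` returns a 16-chromosome genome scaled to the
#' S. cerevisiae nuclear chromosome lengths with approximate centromere
#' midpoints; `test_genome()` is a small two-chromosome genome used to keep
#' simulation-heavy tests fast.
#'
#' @return A `data.frame` with columns `chrom` (character), `length` (bp)
#'   and `centromere` (bp, midpoint position).
#' @examples
#' yeast_genome()
#' @export
yeast_genome <- function() {
  data.frame(
    chrom = paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                            "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")),
    length = c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L,
               1090940L, 562643L, 439888L, 745751L, 666816L, 1078177L,
               924431L, 784333L, 1091291L, 948066L),
    centromere = c(151465L, 238207L, 114385L, 449711L, 151987L, 148510L,
                   496920L, 105586L, 355629L, 436307L, 440129L, 150828L,
                   268031L, 628758L, 326584L, 555957L),
    stringsAsFactors = FALSE
  )
}

#' @rdname yeast_genome
#' @export
test_genome <- function() {
  data.frame(
    chrom = c("chrA", "chrB"),
    length = c(500000L, 300000L),
    centromere = c(120000L, 90000L),
    stringsAsFactors = FALSE
  )
}
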