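#' Construct a trait table
#'
#' A trait table stores non-negative copy numbers of gene families (or the
#' 16S rRNA gene) for a set of genomes or queries, under one annotation
#' framework ("KO", "EC", "16S", ...). The 16S framework is distinguished:
#' it must have exactly one column and every value must be >= 1, because a
#' sequenced genome necessarily carries at least one 16S copy.
#'
#' Zero and absent are semantically identical: most gene families are
#' absent from most genomes, and an absent entry contributes nothing to a
#' predicted metagenome.
#'
#' @param values numeric matrix, rows = genome/query ids, columns = trait
#'   ids; dimnames required.
#' @param framework_id single string naming the annotation framework.
#' @return a `trait_table` object (a numeric matrix with attributes).
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("K00001", "K00002")))
#' tt <- trait_table(m, "KO")
#' @export
trait_table <- function(values, framework_id) {
  if (!is.matrix(values) || !is.numeric(values))
    .fail("trait table values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .fail("trait table requires row (genome) and column (trait) names")
  if (anyDuplicated(rownames(values)))
    .fail("duplicate row ids in trait table: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    .fail("duplicate trait ids in trait table")
  if (!is.character(framework_id) || length(framework_id) != 1L)
    .fail("framework_id must be a single string")
  if (anyNA(values) || any(values < 0))
    .fail("trait table '%s' contains negative or missing values",
          framework_id)
  if (identical(framework_id, "16S")) {
    if (ncol(values) != 1L)
      .fail("the 16S framework must have exactly one trait column")
    if (any(values < 1))
      .fail("16S copy numbers must all be >= 1")
  }
  structure(values, framework_id = framework_id,
            class = c("trait_table", class(values)))
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> framework '%s': %d rows x %d traits\n",
              attr(x, "framework_id"), nrow(x), ncol(x)))
  invisible(x)
}

#' Framework id of a trait table
#' @param x a `trait_table`.
#' @return single string.
#' @export
framework_id <- function(x) attr(x, "framework_id")

#' Subset a trait table to a set of rows, preserving class
#' @noRd
subset_trait_table <- function(x, ids) {
  missing <- setdiff(ids, rownames(x))
  if (length(missing))
    .fail("genomes absent from trait table '%s': %s", framework_id(x),
          paste(missing, collapse = ", "))
  trait_table(unclass(x)[ids, , drop = FALSE], framework_id(x))
}
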