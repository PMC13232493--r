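#' Declare a genome build
#'
#' Every coordinate-bearing object in a project (loci, gene annotation,
#' coordinate-linked evidence) is tagged with a genome build, and operations
#' that combine two of them refuse to proceed unless the builds match
#' exactly. This catches the classic silent failure of joining mm10 evidence
#' onto mm39 genes; inputs on another build must be lifted over before use.
#'
#' @param name Build name, e.g. `"mm39"` or `"GRCh38"`. Equality is exact
#'   string match.
#' @param species Species label, e.g. `"Mus musculus"`.
#' @return A `genome_build` object.
#' @examples
#' genome_build("mm39", "Mus musculus")
#' @export
genome_build <- function(name, species = "") {
  lp_assert(is_string(name) && nzchar(name), "`name` must be a non-empty string")
  lp_assert(is.character(species) && length(species) == 1,
            "`species` must be a single string")
  structure(list(name = name, species = species), class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", x$name,
      if (nzchar(x$species)) paste0(" (", x$species, ")"), "\n", sep = "")
  invisible(x)
}

#' @export
format.genome_build <- function(x, ...) x$name

same_build <- function(a, b) {
  identical(build_name(a), build_name(b))
}

build_name <- function(x) {
  if (inherits(x, "genome_build")) x$name
  else if (is.character(x)) x[[1]]
  else lp_stop("not a genome build")
}

check_same_build <- function(a, b, what = "inputs") {
  if (!same_build(a, b)) {
    lp_stop(
      paste0(
        "genome build mismatch: ", what, " are on '", build_name(a),
        "' vs '", build_name(b), "'. All inputs to a project must share ",
        "one build; convert coordinates (e.g. liftOver) before attaching."
      ),
      class = "lp_build_mismatch"
    )
  }
  invisible(TRUE)
}

# Attribute accessor used across loci/annotation tibbles.
lp_build <- function(x) {
  b <- attr(x, "build", exact = TRUE)
  if (is.null(b)) lp_stop("object carries no genome build tag")
  b
}
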