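# Composition tables with bootstrap standard errors.

#' Bootstrap parameters
#'
#' @param seed integer RNG seed (required for reproducibility).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param unit resampling unit: whole interfaces (default), residues or
#'   atoms. Interface-level resampling reflects the between-interface
#'   variability that dominates small contact-surface statistics.
#' @return a list of class `BootstrapParams`.
#' @export
bootstrap_params <- function(seed, n_boot = 1000,
                             unit = c("interface", "residue", "atom")) {
  stopifnot(n_boot >= 1)
  unit <- match.arg(unit)
  structure(list(seed = as.integer(seed), n_boot = as.integer(n_boot),
                 unit = unit),
            class = "BootstrapParams")
}

#' Composition table
#'
#' Percent composition of a set of items over the categories produced by
#' `category_fn`. Percentages sum to 100.
#'
#' @param items non-empty vector (or list) of items.
#' @param category_fn function mapping `items` to category labels
#'   (vectorized); default identity.
#' @param categories optional fixed category ordering/universe; categories
#'   not present get 0.
#' @return a `CompositionTable`: data frame with `category`, `count`,
#'   `percent`, and attribute `n_items`.
#' @export
composition <- function(items, category_fn = identity, categories = NULL) {
  if (length(items) == 0) stop("composition of an empty item set")
  cats <- as.character(category_fn(items))
  if (is.null(categories)) categories <- sort(unique(cats))
  cnt <- table(factor(cats, levels = categories))
  out <- data.frame(category = categories,
                    count = as.integer(cnt),
                    percent = 100 * as.integer(cnt) / length(cats),
                    stringsAsFactors = FALSE)
  attr(out, "n_items") <- length(cats)
  class(out) <- c("CompositionTable", "data.frame")
  out
}

#' Build a composition table from reported percentages
#'
#' Wraps externally given category percentages (e.g. a published table
#' column) in the `CompositionTable` shape so that group summaries such as
#' [prb_summary()] apply to them.
#'
#' @param categories character vector of category labels.
#' @param percent numeric percentages.
#' @return a `CompositionTable` (with `count = NA`).
#' @export
composition_table <- function(categories, percent) {
  stopifnot(length(categories) == length(percent))
  out <- data.frame(category = as.character(categories), count = NA_integer_,
                    percent = as.numeric(percent), stringsAsFactors = FALSE)
  attr(out, "n_items") <- NA_integer_
  class(out) <- c("CompositionTable", "data.frame")
  out
}

#' Phosphate / ribose / base summary of an atom-type composition
#'
#' Sums the percentages of an atom-name composition table over the
#' phosphate, ribose and base groups of [rna_atom_group()]. The three
#' values sum to the table total (100 for a full table).
#'
#' @param table a `CompositionTable` whose categories are nucleotide atom
#'   names (base atoms may be present explicitly or implied as the
#'   remainder to 100 when `complete = TRUE`).
#' @param complete if `TRUE` (default) and the table lists only backbone
#'   atom names, the base share is taken as `100 - sum(percent)`.
#' @return named numeric vector `c(phosphate=, ribose=, base=)` of percent.
#' @export
prb_summary <- function(table, complete = TRUE) {
  grp <- rna_atom_group(table$category)
  out <- c(phosphate = sum(table$percent[grp == "phosphate"]),
           ribose = sum(table$percent[grp == "ribose"]),
           base = sum(table$percent[grp == "base"]))
  if (complete && !any(grp == "base"))
    out[["base"]] <- 100 - out[["phosphate"]] - out[["ribose"]]
  out
}

#' Bootstrap standard errors of composition percentages
#'
#' Units (by default whole interfaces) are resampled with replacement
#' `n_boot` times; the composition is recomputed on the pooled items of each
#' resample and the SE of each category's percentage is the standard
#' deviation (divisor `n_boot`) of its bootstrap distribution. Identical
#' units give SE 0; fixed seed gives identical SEs.
#'
#' @param groups list of item vectors, one per resampling unit.
#' @param params a [bootstrap_params()] list.
#' @param category_fn as in [composition()].
#' @return named numeric vector of SEs over the union of categories.
#' @export
bootstrap_se <- function(groups, params, category_fn = identity) {
  stopifnot(length(groups) >= 1)
  cats <- sort(unique(as.character(category_fn(unlist(groups,
                                                      use.names = FALSE)))))
  k <- length(groups)
  withr::with_seed(params$seed, {
    boot <- matrix(0, nrow = params$n_boot, ncol = length(cats),
                   dimnames = list(NULL, cats))
    for (b in seq_len(params$n_boot)) {
      pick <- sample.int(k, k, replace = TRUE)
      pooled <- unlist(groups[pick], use.names = FALSE)
      tab <- composition(pooled, category_fn, categories = cats)
      boot[b, ] <- tab$percent
    }
  })
  mu <- colMeans(boot)
  sqrt(colMeans(sweep(boot, 2, mu)^2))
}
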