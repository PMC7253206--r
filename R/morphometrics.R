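#' Fruit shape descriptors
#'
#' Adds the three dimensionless descriptors to a fruit measurement table:
#' aspect ratio `AR = major / minor`, roundness `Ro = 4 A / (pi major^2)`
#' and circularity `Ci = 4 pi A / perimeter^2` (the ImageJ descriptor; a
#' variant replacing the area by the aspect ratio in the numerator is kept
#' behind `circularity = "aspect_ratio"` for audit). All three equal 1 for
#' a perfect circle and are invariant to uniform rescaling.
#'
#' @param measurements Tibble with positive `area`, `major_axis`,
#'   `minor_axis`, `perimeter`.
#' @param circularity `"area"` (default) or `"aspect_ratio"`.
#' @return The table with `aspect_ratio`, `roundness`, `circularity` added.
#' @export
shape_descriptors <- function(measurements, circularity = c("area", "aspect_ratio")) {
  circularity <- match.arg(circularity)
  need <- c("area", "major_axis", "minor_axis", "perimeter")
  if (!all(need %in% names(measurements))) {
    abort(paste0("Need columns: ", paste(need, collapse = ", ")))
  }
  with_cols <- measurements[need]
  if (any(as.matrix(with_cols) <= 0, na.rm = TRUE)) {
    abort("All measurements must be strictly positive.")
  }
  if (any(measurements$major_axis < measurements$minor_axis)) {
    abort("major_axis must be >= minor_axis.")
  }
  ar <- measurements$major_axis / measurements$minor_axis
  ci_num <- if (circularity == "area") measurements$area else ar
  measurements %>%
    mutate(
      aspect_ratio = ar,
      roundness = 4 * .data$area / (pi * .data$major_axis^2),
      circularity = 4 * pi * ci_num / .data$perimeter^2
    )
}

#' Variance-stabilizing transforms for morphometric traits
#'
#' Log10 for the size-like traits (`area`, `major_axis`, `minor_axis`,
#' `perimeter`, `aspect_ratio`); arcsine-square-root for the bounded ratio
#' traits (`roundness`, `circularity`), which are clipped to \[0, 1\] first
#' (with a warning) since measurement noise can push them slightly above 1.
#'
#' @param traits Tibble containing some of the columns above; others pass
#'   through untouched.
#' @return The transformed table.
#' @export
transform_traits <- function(traits) {
  log_traits <- intersect(
    c("area", "major_axis", "minor_axis", "perimeter", "aspect_ratio"),
    names(traits)
  )
  asin_traits <- intersect(c("roundness", "circularity"), names(traits))
  for (v in log_traits) {
    if (any(traits[[v]] <= 0, na.rm = TRUE)) {
      abort(paste0("Nonpositive values in `", v, "` cannot be log10-transformed."))
    }
    traits[[v]] <- log10(traits[[v]])
  }
  for (v in asin_traits) {
    x <- traits[[v]]
    n_clip <- sum(x < 0 | x > 1, na.rm = TRUE)
    if (n_clip > 0) {
      warn(sprintf("%d value(s) of `%s` clipped to [0, 1] before arcsine transform.", n_clip, v))
      x <- pmin(pmax(x, 0), 1)
    }
    traits[[v]] <- asin(sqrt(x))
  }
  traits
}

#' PCA of morphometric traits
#'
#' Principal component analysis of the numeric trait columns, centered and
#' (by default) scaled to unit variance, since transformed traits mix
#' units. Constant columns are dropped with a warning. Loading signs follow
#' a deterministic convention: each component's largest-magnitude loading
#' is positive, making orientations reproducible across runs.
#'
#' @param traits Tibble of (transformed) traits; non-numeric columns such as
#'   `genotype` or `fruit_id` are carried into the score table.
#' @param scale Scale columns to unit variance (default TRUE).
#' @return Object of class `trait_pca`: `scores` (tibble), `loadings`
#'   (tibble, traits x PCs), `variance_explained` (proportions summing
#'   to 1). `tidy()` returns loadings in long form; `glance()` one row of
#'   variance proportions.
#' @export
pca_traits <- function(traits, scale = TRUE) {
  is_num <- vapply(traits, is.numeric, logical(1))
  meta <- traits[!is_num]
  x <- as.matrix(traits[is_num])
  if (ncol(x) < 2 || nrow(x) < 3) abort("PCA needs >= 2 traits and >= 3 observations.")
  const <- apply(x, 2, function(v) sd(v) < .Machine$double.eps^0.5)
  if (any(const)) {
    warn(paste0("Dropping constant trait(s): ", paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = scale)
  # sign convention: dominant loading of each PC is positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(
    scores = dplyr::bind_cols(meta, as_tibble(pc$x)),
    loadings = as_tibble(pc$rotation, rownames = "trait"),
    variance_explained = ve,
    center = pc$center,
    scale = if (isTRUE(scale)) pc$scale else NULL
  )
  class(out) <- "trait_pca"
  out
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait PCA:", nrow(x$loadings), "traits,", nrow(x$scores), "observations\n")
  cat(
    "Variance explained:",
    paste0(sprintf("PC%d %.1f%%", seq_along(x$variance_explained), 100 * x$variance_explained),
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' @rdname pca_traits
#' @param x A `trait_pca` object.
#' @param ... Unused.
#' @method tidy trait_pca
#' @export
tidy.trait_pca <- function(x, ...) {
  x$loadings %>%
    tidyr::pivot_longer(-"trait", names_to = "component", values_to = "loading")
}

#' @rdname pca_traits
#' @method glance trait_pca
#' @export
glance.trait_pca <- function(x, ...) {
  ve <- x$variance_explained
  out <- as_tibble(as.list(setNames(ve, paste0("variance_PC", seq_along(ve)))))
  out$n_components <- length(ve)
  out
}

#' Trait-level dominance between genotypes
#'
#' Collapses a per-fruit trait (or PC score) to per-genotype medians and
#' evaluates additive effect, dominance deviation and degree of dominance
#' via [degree_of_dominance()].
#'
#' @param data Tibble with a genotype column (`W`, `C`, `CxW`) and the trait.
#' @param trait Name of the trait column (string).
#' @param genotype_col Name of the genotype column (default `"genotype"`).
#' @return One-row `dominance_records` tibble.
#' @export
trait_dominance <- function(data, trait, genotype_col = "genotype") {
  g <- data[[genotype_col]]
  if (!all(c("W", "C", "CxW") %in% g)) {
    abort("Need observations for genotypes W, C and CxW.")
  }
  v <- data[[trait]]
  degree_of_dominance(
    W = median(v[g == "W"]),
    C = median(v[g == "C"]),
    F1 = median(v[g == "CxW"]),
    id = trait
  )
}
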