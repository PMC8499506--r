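#' Panel specifications for synthetic targeted assays
#'
#' A panel specification is a `data.frame` with one row per analyte and
#' columns `analyte` (unique name), `class`, `lod` (limit of detection in
#' measurement units) and optionally `missingRate` (per-analyte
#' missing-completely-at-random override). `metabolomicsPanel()` builds a
#' 188-analyte targeted panel (21 amino acids, 40 acylcarnitines, 21
#' biogenic amines, 1 monosaccharide, 90 glycerophospholipids, 15
#' sphingomyelins); `lipidomicsPanel()` builds a 1008-species panel across
#' the 15 classes CE, FFA, MAG, DAG, TAG, LPC, LPE, PC, PE, PI, CER, DCER,
#' HCER, LCER, SM, with species names in a mass-spectrometry
#' class+carbons:bonds nomenclature that [parseLipidName()] understands.
#' Panels can be scaled down for small simulations with `scale`.
#'
#' LODs are drawn reproducibly from the panel seed so that a given call is
#' deterministic.
#'
#' @param scale Fraction in (0, 1] of each class to keep (at least one
#'   analyte per class is retained).
#' @param seed Seed for the LOD draw and species composition.
#' @return A panel specification `data.frame`.
#' @examples
#' head(metabolomicsPanel())
#' nrow(lipidomicsPanel())
#' @name panels
NULL

.panelLods <- function(n, seed) {
  # small LODs relative to simulated abundances (log2 means around 5)
  withr_seed <- .Random.seed_exists()
  set.seed(seed + 7L)
  l <- 2^stats::runif(n, -1, 1)
  .restore_seed(withr_seed)
  l
}

# save/restore the RNG state so panel construction does not perturb
# surrounding simulations
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(saved) {
  if (is.null(saved)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", saved, envir = globalenv())
  invisible(NULL)
}

.scaleCounts <- function(counts, scale) {
  stats::setNames(pmax(1L, as.integer(round(counts * scale))),
                  names(counts))
}

#' @rdname panels
#' @export
metabolomicsPanel <- function(scale = 1, seed = 100L) {
  stopifnot(scale > 0, scale <= 1)
  counts <- c(AA = 21L, AC = 40L, BA = 21L, monosaccharide = 1L,
              glycerophospholipid = 90L, sphingomyelin = 15L)
  counts <- .scaleCounts(counts, scale)
  cls <- rep(names(counts), counts)
  name <- unlist(mapply(function(cl, n) {
    switch(cl,
      AA = paste0("AA_", sprintf("%02d", seq_len(n))),
      AC = paste0("C", sprintf("%02d", seq_len(n)), ".AC"),
      BA = paste0("BA_", sprintf("%02d", seq_len(n))),
      monosaccharide = "H1",
      glycerophospholipid = {
        # Biocrates-style diacyl/acyl-alkyl PC names
        carbons <- rep(seq(28, 42, by = 2), length.out = n)
        bonds <- (seq_len(n) - 1L) %% 5L
        kind <- rep(c("aa", "ae"), length.out = n)
        paste0("PC ", kind, " C", carbons, ":", bonds)
      },
      sphingomyelin = {
        carbons <- rep(seq(16, 26, by = 2), length.out = n)
        bonds <- (seq_len(n) - 1L) %% 3L
        oh <- rep(c("", "(OH) "), length.out = n)
        paste0("SM ", oh, "C", carbons, ":", bonds)
      })
  }, names(counts), counts, SIMPLIFY = FALSE), use.names = FALSE)
  name <- make.unique(name, sep = "#")
  data.frame(analyte = name, class = cls,
             lod = .panelLods(length(name), seed),
             stringsAsFactors = FALSE)
}

# printed per-class species counts; PE reduced so the panel totals 1008
.lipidClassCounts <- c(CE = 26L, FFA = 26L, MAG = 26L, DAG = 59L,
                       TAG = 493L, LPC = 26L, LPE = 26L, PC = 140L,
                       PE = 97L, PI = 28L, CER = 12L, DCER = 13L,
                       HCER = 12L, LCER = 12L, SM = 12L)

.lipidCarbonRange <- list(
  CE = c(14, 26), FFA = c(10, 26), MAG = c(14, 22), DAG = c(28, 40),
  TAG = c(35, 60), LPC = c(14, 22), LPE = c(14, 22), PC = c(28, 44),
  PE = c(28, 44), PI = c(30, 42), CER = c(14, 26), DCER = c(14, 26),
  HCER = c(14, 26), LCER = c(14, 26), SM = c(14, 26))

#' @rdname panels
#' @export
lipidomicsPanel <- function(scale = 1, seed = 200L) {
  stopifnot(scale > 0, scale <= 1)
  counts <- .scaleCounts(.lipidClassCounts, scale)
  saved <- .Random.seed_exists()
  set.seed(seed)
  rows <- lapply(names(counts), function(cl) {
    n <- counts[[cl]]
    rng <- .lipidCarbonRange[[cl]]
    carbons <- sort(sample(seq(rng[1], rng[2]), n, replace = TRUE))
    maxdb <- if (cl == "TAG") 12L else 6L
    bonds <- sapply(carbons, function(cc)
      sample.int(min(maxdb, max(1L, cc %/% 4L)) + 1L, 1L) - 1L)
    if (cl %in% c("TAG", "DAG")) {
      # species resolve one constituent fatty acid
      fac <- pmin(carbons - 4L, sample(c(14L, 16L, 18L, 20L, 22L),
                                       n, replace = TRUE))
      fab <- pmin(bonds, sample(0:2, n, replace = TRUE))
      name <- paste0(cl, carbons, ":", bonds, "-FA", fac, ":", fab)
    } else {
      name <- paste0(cl, carbons, ":", bonds)
    }
    data.frame(analyte = name, class = cl, stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  panel <- panel[!duplicated(panel$analyte), , drop = FALSE]
  # top up classes whose random species collided, keeping counts exact
  for (cl in names(counts)) {
    need <- counts[[cl]] - sum(panel$class == cl)
    while (need > 0) {
      rng <- .lipidCarbonRange[[cl]]
      cc <- sample(seq(rng[1], rng[2]), 1L)
      bb <- sample.int(7L, 1L) - 1L
      nm <- if (cl %in% c("TAG", "DAG"))
        paste0(cl, cc, ":", bb, "-FA", min(cc - 4L, 18L), ":",
               min(bb, 1L))
      else paste0(cl, cc, ":", bb)
      if (!nm %in% panel$analyte) {
        panel <- rbind(panel, data.frame(analyte = nm, class = cl,
                                         stringsAsFactors = FALSE))
        need <- need - 1L
      } else {
        # perturb until unique
        bb2 <- (bb + 1L) %% 7L
        nm2 <- sub(":[0-9]+", paste0(":", bb2), nm)
        if (!nm2 %in% panel$analyte) {
          panel <- rbind(panel, data.frame(analyte = nm2, class = cl,
                                           stringsAsFactors = FALSE))
          need <- need - 1L
        }
      }
    }
  }
  .restore_seed(saved)
  panel <- panel[order(match(panel$class, names(counts)), panel$analyte), ]
  rownames(panel) <- NULL
  panel$lod <- .panelLods(nrow(panel), seed)
  panel
}

.validatePanel <- function(panel) {
  if (!is.data.frame(panel) ||
      !all(c("analyte", "class", "lod") %in% names(panel)))
    stop("panel spec needs columns 'analyte', 'class', 'lod'")
  if (anyDuplicated(panel$analyte))
    stop("panel analyte names must be unique")
  if (any(!is.finite(panel$lod)) || any(panel$lod <= 0))
    stop("every analyte needs a positive LOD")
  invisible(panel)
}
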