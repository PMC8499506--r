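.lipidClasses <- c("CE", "FFA", "MAG", "DAG", "TAG", "LPC", "LPE", "PC",
                   "PE", "PI", "CER", "DCER", "HCER", "LCER", "SM")

#' Parse a lipid or metabolite species name
#'
#' Understands three nomenclature dialects:
#' \itemize{
#'   \item targeted-kit (Biocrates-style) names: `"PC aa C30:0"`,
#'     `"PC ae C38:3"`, `"lysoPC a C18:2"`, `"SM C24:1"`, `"SM (OH) C22:2"`;
#'   \item lipidomics-panel (Metabolon-style) names:
#'     `"TAG52:2-FA18:1"`, `"DAG36:2-FA18:1"`, `"CE16:0"`, `"PE38:4"`;
#'   \item total fatty acids: `"FA 16:0"`.
#' }
#' The total carbon count, total double-bond count, the class (mapped into
#' the 15-class lipidomics vocabulary where applicable: `lysoPC` -> LPC,
#' `lysoPE` -> LPE, `FA` -> FFA) and any stated fatty-acid constituent are
#' returned.
#'
#' @param name Species name string (vectorized).
#' @return For a single name, a list with `species`, `class`, `carbons`,
#'   `doubleBonds`, `faComponents` (list of `c(carbons, doubleBonds)`),
#'   `dialect`; for a vector, a `data.frame` with one row per name and
#'   `faCarbons`/`faDoubleBonds` columns (NA when unstated).
#' @examples
#' parseLipidName("PC aa C30:0")
#' parseLipidName("TAG52:2-FA18:1")
#' @export
parseLipidName <- function(name) {
  if (length(name) > 1L) {
    rows <- lapply(name, function(nm) {
      p <- parseLipidName(nm)
      data.frame(species = p$species, class = p$class, carbons = p$carbons,
                 doubleBonds = p$doubleBonds,
                 faCarbons = if (length(p$faComponents))
                   p$faComponents[[1]][1] else NA_integer_,
                 faDoubleBonds = if (length(p$faComponents))
                   p$faComponents[[1]][2] else NA_integer_,
                 dialect = p$dialect, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  nm <- trimws(name)

  # Biocrates-style: "PC aa C30:0", "lysoPC a C18:2", "SM (OH) C22:2"
  m <- regmatches(nm, regexec(
    "^(PC|PE|SM|lysoPC|lysoPE)( aa| ae| a)?( \\(OH\\))? C([0-9]+):([0-9]+)$",
    nm))[[1]]
  if (length(m)) {
    cls <- switch(m[2], lysoPC = "LPC", lysoPE = "LPE", m[2])
    return(.lipidAnnotation(nm, cls, as.integer(m[5]), as.integer(m[6]),
                            list(), "biocrates"))
  }

  # total fatty acid: "FA 16:0"
  m <- regmatches(nm, regexec("^FA ?([0-9]+):([0-9]+)$", nm))[[1]]
  if (length(m))
    return(.lipidAnnotation(nm, "FFA", as.integer(m[2]), as.integer(m[3]),
                            list(c(as.integer(m[2]), as.integer(m[3]))),
                            "fa"))

  # Metabolon-style: "TAG52:2-FA18:1", "CE(16:0)", "PE38:4"
  m <- regmatches(nm, regexec(paste0(
    "^(", paste(.lipidClasses, collapse = "|"),
    ")\\(?([0-9]+):([0-9]+)\\)?(-FA([0-9]+):([0-9]+))?$"), nm))[[1]]
  if (length(m)) {
    fa <- if (nzchar(m[5]))
      list(c(as.integer(m[6]), as.integer(m[7]))) else list()
    return(.lipidAnnotation(nm, m[2], as.integer(m[3]), as.integer(m[4]),
                            fa, "metabolon"))
  }

  stop("cannot parse species name '", name, "'; dialects tried: ",
       "targeted-kit ('PC aa C30:0', 'SM (OH) C22:2'), ",
       "fatty acid ('FA 16:0'), ",
       "lipidomics panel ('TAG52:2-FA18:1', 'CE16:0')")
}

.lipidAnnotation <- function(species, cls, carbons, bonds, fa, dialect) {
  if (carbons < 1) stop("carbon count must be positive in '", species, "'")
  # each double bond needs two carbons
  if (bonds > carbons %/% 2)
    stop("infeasible double-bond count in '", species, "'")
  list(species = species, class = cls, carbons = carbons,
       doubleBonds = bonds, faComponents = fa, dialect = dialect)
}

#' Canonical form of a parsed lipid name
#'
#' Inverse of [parseLipidName()]: renders the annotation back in its own
#' dialect's canonical spelling, so `formatLipidName(parseLipidName(x))`
#' round-trips canonical names.
#'
#' @param annotation Result of [parseLipidName()] (single name).
#' @return Character scalar.
#' @export
formatLipidName <- function(annotation) {
  cb <- paste0(annotation$carbons, ":", annotation$doubleBonds)
  switch(annotation$dialect,
    fa = paste0("FA ", cb),
    biocrates = annotation$species,  # qualifier (aa/ae/OH) kept verbatim
    metabolon = {
      fa <- annotation$faComponents
      base <- paste0(annotation$class, cb)
      if (length(fa)) paste0(base, "-FA", fa[[1]][1], ":", fa[[1]][2])
      else base
    },
    stop("unknown dialect '", annotation$dialect, "'"))
}

#' Chain-length bin of a fatty-acid carbon count
#'
#' Standard lipid-chemistry convention: medium-chain < 14 carbons,
#' long-chain 14-20 inclusive, very-long-chain >= 22.
#'
#' @param carbons Integer vector of carbon counts.
#' @return Factor with levels medium/long/very-long.
#' @export
chainLengthBin <- function(carbons) {
  cut(carbons, breaks = c(-Inf, 13.5, 21, Inf),
      labels = c("medium", "long", "very-long"))
}

#' Aggregate differential-abundance results on the structure grid
#'
#' Keys each annotated species by (class, total carbons, total double
#' bonds) and summarizes every occupied cell: median log2 fold change,
#' member count, and significance flags (a cell is flagged when at least
#' one member species has FDR below `alpha`, matching species-level
#' significance display). Species without an annotation are excluded with a
#' warning and listed in the `unannotated` attribute.
#'
#' @param de `data.frame` from [weightedDiffAbundance()] (columns `analyte`,
#'   `log2FC`, `FDR`).
#' @param annotations `data.frame` keyed by `species` with `class`,
#'   `carbons`, `doubleBonds` (e.g. `parseLipidName(de$analyte)`).
#' @param alpha Significance threshold on FDR (default 0.05).
#' @return `data.frame` with one row per occupied (class, carbons,
#'   doubleBonds) cell: `n`, `medianLog2FC`, `minFDR`, `significant`,
#'   `flag` in {up, down, ns}.
#' @export
aggregateByStructure <- function(de, annotations, alpha = 0.05) {
  if (!nrow(de)) {
    out <- data.frame(class = character(), carbons = integer(),
                      doubleBonds = integer(), n = integer(),
                      medianLog2FC = numeric(), minFDR = numeric(),
                      significant = logical(), flag = character())
    attr(out, "unannotated") <- character()
    return(out)
  }
  idx <- match(de$analyte, annotations$species)
  unannotated <- de$analyte[is.na(idx)]
  if (length(unannotated))
    warning(length(unannotated), " species lack annotations and were ",
            "excluded (see attr(,'unannotated'))")
  keep <- !is.na(idx)
  d <- cbind(de[keep, c("analyte", "log2FC", "FDR")],
             annotations[idx[keep], c("class", "carbons", "doubleBonds")])
  key <- interaction(d$class, d$carbons, d$doubleBonds, drop = TRUE)
  cells <- lapply(split(d, key), function(g) {
    sig <- g$FDR < alpha & !is.na(g$FDR)
    data.frame(class = g$class[1], carbons = g$carbons[1],
               doubleBonds = g$doubleBonds[1], n = nrow(g),
               medianLog2FC = stats::median(g$log2FC, na.rm = TRUE),
               minFDR = suppressWarnings(min(g$FDR, na.rm = TRUE)),
               significant = any(sig),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cells)
  out$flag <- ifelse(!out$significant, "ns",
                     ifelse(out$medianLog2FC >= 0, "up", "down"))
  out <- out[order(out$class, out$carbons, out$doubleBonds), ]
  rownames(out) <- NULL
  attr(out, "unannotated") <- unannotated
  out
}

#' Class-by-fatty-acid composition matrix
#'
#' For every (lipid class, constituent fatty acid) pair, summarizes the
#' member species: median log2 fold change and a flag among
#' `significant-up`, `significant-down`, `not-significant`, `not-detected`
#' (no member species). A cell is significant when at least one member has
#' FDR below `alpha`; its direction is the sign of the median fold change.
#'
#' @inheritParams aggregateByStructure
#' @param annotations Must carry `faCarbons`/`faDoubleBonds` (or a
#'   `faComponents` list column).
#' @param classes Classes forming the rows (default: the 15-class
#'   vocabulary).
#' @return List with `log2FC` (classes x FA matrix) and `flag` (character
#'   matrix, same shape).
#' @export
fattyAcidCompositionMatrix <- function(de, annotations, alpha = 0.05,
                                       classes = .lipidClasses) {
  idx <- match(de$analyte, annotations$species)
  keep <- !is.na(idx)
  d <- cbind(de[keep, c("analyte", "log2FC", "FDR")],
             annotations[idx[keep], , drop = FALSE])
  d <- d[!is.na(d$faCarbons), , drop = FALSE]
  d$fa <- paste0("FA ", d$faCarbons, ":", d$faDoubleBonds)
  fas <- unique(d$fa[order(d$faCarbons, d$faDoubleBonds)])
  l2 <- matrix(NA_real_, length(classes), length(fas),
               dimnames = list(classes, fas))
  flag <- matrix("not-detected", length(classes), length(fas),
                 dimnames = list(classes, fas))
  for (g in split(d, list(d$class, d$fa), drop = TRUE)) {
    cl <- as.character(g$class[1]); fa <- g$fa[1]
    if (!cl %in% classes) next
    med <- stats::median(g$log2FC, na.rm = TRUE)
    sig <- any(g$FDR < alpha, na.rm = TRUE)
    l2[cl, fa] <- med
    flag[cl, fa] <- if (!sig) "not-significant" else
      if (med >= 0) "significant-up" else "significant-down"
  }
  list(log2FC = l2, flag = flag)
}
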