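# Genotype representation and Mendelian machinery for the engineered loci.
#
# Four loci are tracked: an X-linked female-lethal construct (FL), the
# refactored pyramus promoter (res) on chromosome 2, the PTA expression
# cassette (PTA) on chromosome 3, and a dominant-lethal RIDL cassette on a
# fourth, independent autosome.  Each engineered element is modelled as a
# single allele; loci assort independently.

.X_ALLELES    <- c("FL", "+")
.PYR_ALLELES  <- c("res", "wt")
.PTA_ALLELES  <- c("PTA", "+")
.RIDL_ALLELES <- c("RIDL", "+")

.canon_pair <- function(pair, levels) {
  # canonical order: engineered allele first (the order of `levels`)
  pair[order(match(pair, levels))]
}

#' Construct a genotype
#'
#' A genotype records the sex-chromosome karyotype, the X-linked
#' female-lethal (FL) allele(s), and unordered diploid allele pairs at the
#' three autosomal loci: the \emph{pyramus} promoter (\code{"res"} =
#' PTA-resistant refactored promoter, \code{"wt"} = wild type), the PTA
#' cassette (\code{"PTA"} or \code{"+"}), and the RIDL cassette
#' (\code{"RIDL"} or \code{"+"}).
#'
#' @param karyotype \code{"XX"} or \code{"XY"}.
#' @param x character vector of X-linked alleles from \code{c("FL", "+")};
#'   length 2 for XX, length 1 for XY.
#' @param pyr,pta,ridl length-2 character vectors (unordered allele pairs).
#' @return An object of class \code{ssims_genotype}.
#' @examples
#' genotype("XY", "FL", c("res", "res"), c("PTA", "PTA"), c("+", "+"))
#' @export
genotype <- function(karyotype, x, pyr = c("wt", "wt"), pta = c("+", "+"),
                     ridl = c("+", "+")) {
  if (!is.character(karyotype) || length(karyotype) != 1L ||
      !karyotype %in% c("XX", "XY"))
    stop("karyotype must be \"XX\" or \"XY\"", call. = FALSE)
  n_x <- if (karyotype == "XX") 2L else 1L
  if (length(x) != n_x)
    stop(sprintf("%s individuals carry exactly %d X allele(s)", karyotype, n_x),
         call. = FALSE)
  chk <- function(v, set, nm, n = 2L) {
    if (length(v) != n || !all(v %in% set))
      stop(sprintf("%s alleles must be %d values from {%s}", nm, n,
                   paste(set, collapse = ", ")), call. = FALSE)
    v
  }
  g <- structure(list(
    karyotype = karyotype,
    x    = .canon_pair(chk(x, .X_ALLELES, "x", n_x), .X_ALLELES),
    pyr  = .canon_pair(chk(pyr, .PYR_ALLELES, "pyr"), .PYR_ALLELES),
    pta  = .canon_pair(chk(pta, .PTA_ALLELES, "pta"), .PTA_ALLELES),
    ridl = .canon_pair(chk(ridl, .RIDL_ALLELES, "ridl"), .RIDL_ALLELES)
  ), class = "ssims_genotype")
  g
}

#' @export
print.ssims_genotype <- function(x, ...) {
  cat(format(x), " [", classify(x), ", ", sex_of(x), "]\n", sep = "")
  invisible(x)
}

#' Serialize a genotype to its compact string code
#'
#' The dialect is \code{"XFL/Y;res,res;PTA,PTA;+,+"}: X alleles (with
#' \code{Y} for the male second slot), then the pyr, PTA and RIDL allele
#' pairs.  \code{parse_genotype()} inverts it losslessly.
#'
#' @param x an \code{ssims_genotype}.
#' @param ... unused.
#' @export
format.ssims_genotype <- function(x, ...) {
  xs <- paste0("X", x$x)
  if (x$karyotype == "XY") xs <- c(xs, "Y")
  paste(paste(xs, collapse = "/"),
        paste(x$pyr, collapse = ","),
        paste(x$pta, collapse = ","),
        paste(x$ridl, collapse = ","),
        sep = ";")
}

#' Parse a genotype string code
#'
#' @param code a string such as \code{"XFL/Y;res,res;PTA,PTA;+,+"}.
#' @return An \code{ssims_genotype}.
#' @seealso [format.ssims_genotype()]
#' @export
parse_genotype <- function(code) {
  if (!is.character(code) || length(code) != 1L)
    stop("code must be a single string", call. = FALSE)
  parts <- strsplit(code, ";", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    stop("malformed genotype code: ", code, call. = FALSE)
  xs <- strsplit(parts[1], "/", fixed = TRUE)[[1]]
  if (length(xs) != 2L) stop("malformed sex-chromosome field: ", parts[1],
                             call. = FALSE)
  karyotype <- if (xs[2] == "Y") "XY" else "XX"
  x_alleles <- sub("^X", "", xs[xs != "Y"])
  pair <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  genotype(karyotype, x_alleles, pair(parts[2]), pair(parts[3]),
           pair(parts[4]))
}

#' Reference strain genotypes
#'
#' Templates for the strains handled by the simulator: wild type
#' (\code{"WT"}), the combined sex-sorting incompatible male system
#' (\code{"SSIMS"}: FL on every X, homozygous refactored promoter, homozygous
#' PTA), the incompatibility-only line (\code{"EGI"}), the female-lethal-only
#' line (\code{"FL"}), and a homozygous dominant-lethal line (\code{"RIDL"}).
#'
#' @param strain one of \code{"WT"}, \code{"SSIMS"}, \code{"EGI"},
#'   \code{"FL"}, \code{"RIDL"}.
#' @param sex \code{"female"} or \code{"male"}.
#' @return An \code{ssims_genotype}.
#' @examples
#' strain_genotype("SSIMS", "male")
#' @export
strain_genotype <- function(strain = c("WT", "SSIMS", "EGI", "FL", "RIDL"),
                            sex = c("female", "male")) {
  strain <- match.arg(strain)
  sex <- match.arg(sex)
  karyotype <- if (sex == "female") "XX" else "XY"
  n_x <- if (sex == "female") 2L else 1L
  x_al <- if (strain %in% c("SSIMS", "FL")) "FL" else "+"
  genotype(karyotype,
           rep(x_al, n_x),
           pyr  = if (strain %in% c("SSIMS", "EGI")) c("res", "res") else c("wt", "wt"),
           pta  = if (strain %in% c("SSIMS", "EGI")) c("PTA", "PTA") else c("+", "+"),
           ridl = if (strain == "RIDL") c("RIDL", "RIDL") else c("+", "+"))
}

#' Enumerate the gametes of a genotype
#'
#' Mendelian segregation with independent assortment across the sex
#' chromosome and the three autosomal loci.  XX parents emit only X-bearing
#' gametes; XY parents emit X- and Y-bearing gametes with probability 0.5
#' each.
#'
#' @param parent an \code{ssims_genotype}.
#' @return A data frame with columns \code{x} (the transmitted X allele, or
#'   \code{"Y"}), \code{pyr}, \code{pta}, \code{ridl} and \code{prob};
#'   probabilities sum to 1.
#' @examples
#' enumerate_gametes(strain_genotype("SSIMS", "male"))
#' @export
enumerate_gametes <- function(parent) {
  if (!inherits(parent, "ssims_genotype"))
    stop("parent must be an ssims_genotype", call. = FALSE)
  locus <- function(pair) {
    u <- unique(pair)
    data.frame(allele = u, p = if (length(u) == 1L) 1 else rep(0.5, 2),
               stringsAsFactors = FALSE)
  }
  sex_chrom <- if (parent$karyotype == "XX") {
    locus(parent$x)
  } else {
    data.frame(allele = c(parent$x, "Y"), p = c(0.5, 0.5),
               stringsAsFactors = FALSE)
  }
  g <- expand.grid(i = seq_len(nrow(sex_chrom)),
                   j = seq_len(nrow(locus(parent$pyr))),
                   k = seq_len(nrow(locus(parent$pta))),
                   l = seq_len(nrow(locus(parent$ridl))))
  py <- locus(parent$pyr); pt <- locus(parent$pta); rd <- locus(parent$ridl)
  out <- data.frame(
    x    = sex_chrom$allele[g$i],
    pyr  = py$allele[g$j],
    pta  = pt$allele[g$k],
    ridl = rd$allele[g$l],
    prob = sex_chrom$p[g$i] * py$p[g$j] * pt$p[g$k] * rd$p[g$l],
    stringsAsFactors = FALSE
  )
  out[out$prob > 0, , drop = FALSE]
}

.as_gamete <- function(row) {
  list(x = row$x, pyr = row$pyr, pta = row$pta, ridl = row$ridl)
}

#' Fuse an egg and a sperm into a zygote genotype
#'
#' @param egg,sperm gametes: lists (or single data-frame rows) with fields
#'   \code{x}, \code{pyr}, \code{pta}, \code{ridl}.  The egg must carry an X
#'   (\code{x} is \code{"FL"} or \code{"+"}); the sperm may carry
#'   \code{"Y"} instead.
#' @return The zygote \code{ssims_genotype}; karyotype is XX iff the sperm
#'   carries an X.
#' @export
fertilize <- function(egg, sperm) {
  egg <- as.list(egg); sperm <- as.list(sperm)
  if (identical(egg$x, "Y"))
    stop("egg gametes cannot carry a Y chromosome", call. = FALSE)
  if (!egg$x %in% .X_ALLELES)
    stop("egg must carry an X allele from {FL, +}", call. = FALSE)
  if (identical(sperm$x, "Y")) {
    genotype("XY", egg$x, c(egg$pyr, sperm$pyr), c(egg$pta, sperm$pta),
             c(egg$ridl, sperm$ridl))
  } else {
    genotype("XX", c(egg$x, sperm$x), c(egg$pyr, sperm$pyr),
             c(egg$pta, sperm$pta), c(egg$ridl, sperm$ridl))
  }
}

#' EGI viability of a genotype
#'
#' The PTA is haplosufficient for lethality and the refactored-promoter
#' resistance allele is haploinsufficient: a zygote dies iff it carries at
#' least one PTA allele together with at least one wild-type (PTA-bindable)
#' \emph{pyramus} promoter allele.  Lethality acts at egg hatch.
#'
#' @param g an \code{ssims_genotype}.
#' @return \code{TRUE} if viable under the incompatibility rule.
#' @export
egi_viable <- function(g) {
  if (!inherits(g, "ssims_genotype")) stop("g must be an ssims_genotype",
                                           call. = FALSE)
  !(any(g$pta == "PTA") && any(g$pyr == "wt"))
}

#' RIDL viability of a genotype at a given food tetracycline level
#'
#' The RIDL cassette is a dominant lethal repressed by dietary tetracycline:
#' a carrier of either sex dies before adulthood when the food concentration
#' is below the repression threshold (the same threshold,
#' \code{p$e_floor}, below which the female-lethal circuit fires).
#'
#' @param g an \code{ssims_genotype}.
#' @param food_tet food tetracycline concentration (ug/ml), >= 0.
#' @param p a [tet_params()] object supplying the repression threshold.
#' @return \code{TRUE} if viable.
#' @export
ridl_viable <- function(g, food_tet, p = tet_params()) {
  if (!inherits(g, "ssims_genotype")) stop("g must be an ssims_genotype",
                                           call. = FALSE)
  if (!is.numeric(food_tet) || length(food_tet) != 1L || is.na(food_tet) ||
      food_tet < 0)
    stop("food_tet must be a single non-negative number", call. = FALSE)
  !(any(g$ridl == "RIDL") && food_tet < p$e_floor)
}

#' Sex of a genotype
#'
#' @param g an \code{ssims_genotype}.
#' @return \code{"female"} (XX) or \code{"male"} (XY).
#' @export
sex_of <- function(g) {
  if (!inherits(g, "ssims_genotype")) stop("g must be an ssims_genotype",
                                           call. = FALSE)
  if (g$karyotype == "XX") "female" else "male"
}

#' Classify a genotype into a strain label
#'
#' Labels are assigned by the first matching rule: \code{WT} (no engineered
#' alleles), \code{SSIMS} (FL on every X, homozygous res, homozygous PTA),
#' \code{EGI} (homozygous res and PTA without FL), \code{FL} (FL-bearing
#' without PTA), \code{RIDL} (RIDL-bearing), else \code{OTHER} (e.g. EGI/WT
#' hybrids carrying one PTA copy).
#'
#' @param g an \code{ssims_genotype}.
#' @return One of \code{"WT"}, \code{"SSIMS"}, \code{"EGI"}, \code{"FL"},
#'   \code{"RIDL"}, \code{"OTHER"}.
#' @export
classify <- function(g) {
  if (!inherits(g, "ssims_genotype")) stop("g must be an ssims_genotype",
                                           call. = FALSE)
  has_fl   <- any(g$x == "FL")
  all_fl   <- all(g$x == "FL")
  res_hom  <- all(g$pyr == "res")
  pta_hom  <- all(g$pta == "PTA")
  any_pta  <- any(g$pta == "PTA")
  any_res  <- any(g$pyr == "res")
  has_ridl <- any(g$ridl == "RIDL")
  if (!has_fl && !any_pta && !any_res && !has_ridl) return("WT")
  if (all_fl && res_hom && pta_hom) return("SSIMS")
  if (!has_fl && res_hom && pta_hom) return("EGI")
  if (has_fl && !any_pta) return("FL")
  if (has_ridl) return("RIDL")
  "OTHER"
}

#' Exhaustive offspring distribution of a cross
#'
#' Forms the outer product of the two parents' gamete distributions and
#' aggregates identical zygote genotypes.  The EGI viability flag is attached
#' per genotype, so e.g. an incompatible-male x wild-type cross shows an
#' inviable fraction of 1.
#'
#' @param mother an XX \code{ssims_genotype}.
#' @param father an XY \code{ssims_genotype}.
#' @return A data frame with columns \code{genotype} (string code),
#'   \code{probability} (summing to 1), and \code{egi_viable}.
#' @examples
#' cross_distribution(strain_genotype("WT", "female"),
#'                    strain_genotype("SSIMS", "male"))
#' @export
cross_distribution <- function(mother, father) {
  if (!inherits(mother, "ssims_genotype") || !inherits(father, "ssims_genotype"))
    stop("mother and father must be ssims_genotype objects", call. = FALSE)
  if (mother$karyotype != "XX" || father$karyotype != "XY")
    stop("cross requires an XX mother and an XY father", call. = FALSE)
  eggs <- enumerate_gametes(mother)
  sperm <- enumerate_gametes(father)
  codes <- character(0); probs <- numeric(0); viable <- logical(0)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(eggs))) {
    for (j in seq_len(nrow(sperm))) {
      z <- fertilize(eggs[i, ], sperm[j, ])
      code <- format(z)
      p <- eggs$prob[i] * sperm$prob[j]
      if (is.null(acc[[code]])) {
        acc[[code]] <- list(p = p, v = egi_viable(z))
      } else {
        acc[[code]]$p <- acc[[code]]$p + p
      }
    }
  }
  codes <- ls(acc)
  out <- data.frame(
    genotype = codes,
    probability = vapply(codes, function(k) acc[[k]]$p, numeric(1)),
    egi_viable = vapply(codes, function(k) acc[[k]]$v, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$probability, out$genotype), , drop = FALSE]
}
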