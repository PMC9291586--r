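#' sdturnover: sex-determination turnover under sexually antagonistic
#' selection and epistasis
#'
#' Deterministic two-sex recursion model for transitions between genetic
#' sex-determination (SD) systems. The diploid genome has four linkage
#' groups: XY, I^A and II^W each carry one SD locus (focal alleles Y, A and
#' W) linked to one sexually antagonistic (SA) locus (focal alleles SA^Y,
#' SA^A, SA^W), and a fourth group carries a single autosomal locus (EPI)
#' that interacts epistatically with one SA locus to modify male fitness.
#' Every locus is biallelic (non-focal allele "+").
#'
#' The main entry points are [run_transition()] for a single invasion
#' scenario, [run_sweep()] for seeded parameter sweeps, and
#' [estimate_boundary()] for mapping turnover boundaries in parameter
#' space.
#'
#' @useDynLib sdturnover, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# Gamete encoding -------------------------------------------------------
#
# A gamete (haplotype) is one allele at each of the 7 loci. Loci are
# assigned bits in a fixed order, least-significant bit first:
#
#   bit 1: XY.SD   (focal allele Y)
#   bit 2: XY.SA   (focal allele SA^Y)
#   bit 3: IA.SD   (focal allele A)
#   bit 4: IA.SA   (focal allele SA^A)
#   bit 5: IIW.SD  (focal allele W)
#   bit 6: IIW.SA  (focal allele SA^W)
#   bit 7: EPI     (focal allele EPI)
#
# The gamete index is the integer 0..127 whose binary expansion holds the
# focal-allele indicators, so index 0 is the all-"+" gamete and index 1
# carries only Y. This bijection is fixed so that trajectory and sweep
# outputs are comparable across runs and implementations.

#' Locus table for the model genome
#'
#' Seven biallelic loci over four linkage groups. The `bit` column gives
#' each locus's position in the gamete-index encoding (least-significant
#' bit first); `locus` names the focal allele.
#'
#' @return A tibble with columns `locus`, `bit`, `linkage_group`, `role`.
#' @examples
#' sd_loci()
#' @export
sd_loci <- function() {
  tibble::tibble(
    locus = c("Y", "SAY", "A", "SAA", "W", "SAW", "EPI"),
    bit = 1:7,
    linkage_group = c("XY", "XY", "IA", "IA", "IIW", "IIW", "EPI"),
    role = c("SD", "SA", "SD", "SA", "SD", "SA", "EPI")
  )
}

#' All locus names in bit order
#' @noRd
LOCUS_NAMES <- c("Y", "SAY", "A", "SAA", "W", "SAW", "EPI")

#' Number of gamete types (2^7)
#' @noRd
N_GAMETES <- 128L

#' Decode gamete indices into a focal-allele indicator matrix
#'
#' @param gametes Integer vector of gamete indices in `0:127` (default all
#'   128 types).
#' @return A 0/1 integer matrix with one row per gamete and one column per
#'   locus (columns named `Y`, `SAY`, `A`, `SAA`, `W`, `SAW`, `EPI`).
#' @examples
#' gamete_alleles(c(0L, 1L, 5L))
#' @export
gamete_alleles <- function(gametes = 0:127) {
  stopifnot(all(gametes >= 0L), all(gametes <= 127L))
  m <- vapply(1:7, function(b) bitwAnd(as.integer(gametes), bitwShiftL(1L, b - 1L)) > 0L,
              integer(length(gametes)))
  m <- matrix(as.integer(m), nrow = length(gametes), ncol = 7L)
  colnames(m) <- LOCUS_NAMES
  rownames(m) <- gamete_label(gametes)
  m
}

#' Human-readable gamete labels
#'
#' Concatenates the focal-allele names carried by each gamete, `"+"` for
#' the all-non-focal gamete.
#'
#' @param gametes Integer vector of gamete indices in `0:127`.
#' @return Character vector of labels.
#' @examples
#' gamete_label(c(0L, 1L, 3L))
#' @export
gamete_label <- function(gametes) {
  vapply(as.integer(gametes), function(g) {
    on <- LOCUS_NAMES[bitwAnd(g, bitwShiftL(1L, 0:6)) > 0L]
    if (length(on) == 0L) "+" else paste(on, collapse = ".")
  }, character(1))
}

#' Build a gamete index from focal-allele names
#'
#' @param ... Character names of focal alleles carried by the gamete
#'   (subset of `Y`, `SAY`, `A`, `SAA`, `W`, `SAW`, `EPI`); no arguments
#'   gives the all-`+` gamete.
#' @return A single gamete index in `0:127`.
#' @examples
#' gamete("Y", "SAY")
#' @export
gamete <- function(...) {
  alleles <- c(...)
  if (length(alleles) == 0L) return(0L)
  idx <- match(alleles, LOCUS_NAMES)
  if (anyNA(idx)) {
    stop("unknown allele name(s): ", paste(alleles[is.na(idx)], collapse = ", "))
  }
  sum(bitwShiftL(1L, idx - 1L))
}

# Sex determination ------------------------------------------------------

#' Sex of a genotype
#'
#' W is a dominant female determiner that overrides Y and A; in the absence
#' of W, any male-determining allele (Y or A) makes a male; with no SD
#' focal allele at all the individual is female (the ancestral XX state).
#' Parental origin is irrelevant to sex.
#'
#' @param maternal,paternal Integer vectors of gamete indices (recycled to
#'   a common length). `maternal` is the egg-derived haplotype, `paternal`
#'   the sperm-derived one.
#' @return Character vector, `"female"` or `"male"`.
#' @examples
#' sex_of(gamete(), gamete())            # +/+ everywhere -> female
#' sex_of(gamete(), gamete("Y"))         # Y/+            -> male
#' sex_of(gamete("W"), gamete("Y"))      # W overrides Y  -> female
#' @export
sex_of <- function(maternal, paternal) {
  n <- max(length(maternal), length(paternal))
  maternal <- rep_len(as.integer(maternal), n)
  paternal <- rep_len(as.integer(paternal), n)
  both <- bitwOr(maternal, paternal)
  has_w <- bitwAnd(both, bitwShiftL(1L, 4L)) > 0L      # W bit
  has_male <- bitwAnd(both, bitwOr(1L, bitwShiftL(1L, 2L))) > 0L  # Y or A bit
  ifelse(has_w, "female", ifelse(has_male, "male", "female"))
}

# Sexually antagonistic fitness ------------------------------------------

#' Parameters of one sexually antagonistic locus
#'
#' Genotype fitness at one SA locus is 1, `1 + h_sex * s_sex` and
#' `1 + s_sex` for 0, 1 and 2 focal-allele copies. An active SA locus has
#' opposite-signed effects in the two sexes (`sM * sF < 0`); an inert locus
#' has `sM = sF = 0`.
#'
#' @param sM,sF Homozygous selection coefficients in males and females;
#'   both must be `> -1`.
#' @param hM,hF Sex-specific dominance coefficients in `[0, 1]`.
#' @return An object of class `sa_params`.
#' @examples
#' sa_params(sM = 0.04, sF = -0.04)
#' @export
sa_params <- function(sM = 0, sF = 0, hM = 0.6, hF = 0.4) {
  stopifnot(length(sM) == 1L, length(sF) == 1L, length(hM) == 1L, length(hF) == 1L)
  if (sM <= -1 || sF <= -1) {
    stop("selection coefficients must exceed -1 (fitness must stay positive)")
  }
  if (hM < 0 || hM > 1 || hF < 0 || hF > 1) {
    stop("dominance coefficients must lie in [0, 1]")
  }
  if (!((sM == 0 && sF == 0) || sM * sF < 0)) {
    stop("an SA locus must be sexually antagonistic (sM * sF < 0) or inert (sM = sF = 0)")
  }
  structure(list(sM = sM, sF = sF, hM = hM, hF = hF), class = "sa_params")
}

#' @export
print.sa_params <- function(x, ...) {
  cat(sprintf("<sa_params> sM = %g, sF = %g, hM = %g, hF = %g\n",
              x$sM, x$sF, x$hM, x$hF))
  invisible(x)
}

#' Fitness factor contributed by one SA locus
#'
#' @param focal_copies Integer vector of focal-allele copy numbers
#'   (0, 1 or 2).
#' @param sex `"male"` or `"female"` (recycled).
#' @param params An [sa_params()] object.
#' @return Numeric vector of positive fitness factors.
#' @examples
#' locus_fitness(0:2, "male", sa_params(sM = 0.04, sF = -0.04))
#' @export
locus_fitness <- function(focal_copies, sex, params) {
  stopifnot(inherits(params, "sa_params"), all(focal_copies %in% 0:2))
  n <- max(length(focal_copies), length(sex))
  focal_copies <- rep_len(as.integer(focal_copies), n)
  sex <- rep_len(sex, n)
  s <- ifelse(sex == "male", params$sM, params$sF)
  h <- ifelse(sex == "male", params$hM, params$hF)
  ifelse(focal_copies == 0L, 1,
         ifelse(focal_copies == 1L, 1 + h * s, 1 + s))
}

#' Sex-specific fitness scheme over the three SA loci
#'
#' Defaults follow the model's standard parameterisation: the
#' male-beneficial loci SA^Y and SA^A have `hM = 0.6`, `hF = 0.4`; the
#' female-beneficial locus SA^W has the mirrored `hM = 0.4`, `hF = 0.6`,
#' so the focal allele is always partially dominant in the sex it benefits.
#' Total fitness is the product of the three per-locus factors.
#'
#' @param SAY,SAA,SAW [sa_params()] objects for the three SA loci.
#' @return An object of class `fitness_scheme`.
#' @examples
#' fitness_scheme(SAY = sa_params(sM = 0.03, sF = -0.03))
#' @export
fitness_scheme <- function(SAY = sa_params(hM = 0.6, hF = 0.4),
                           SAA = sa_params(hM = 0.6, hF = 0.4),
                           SAW = sa_params(hM = 0.4, hF = 0.6)) {
  stopifnot(inherits(SAY, "sa_params"), inherits(SAA, "sa_params"),
            inherits(SAW, "sa_params"))
  for (nm in c("SAY", "SAA")) {
    p <- get(nm)
    if (!(p$sM == 0 && p$sF == 0) && !(p$sM > 0 && p$sF < 0)) {
      stop(nm, " must be male-beneficial (sM > 0, sF < 0) or inert")
    }
  }
  if (!(SAW$sM == 0 && SAW$sF == 0) && !(SAW$sF > 0 && SAW$sM < 0)) {
    stop("SAW must be female-beneficial (sF > 0, sM < 0) or inert")
  }
  structure(list(SAY = SAY, SAA = SAA, SAW = SAW), class = "fitness_scheme")
}

#' @export
print.fitness_scheme <- function(x, ...) {
  cat("<fitness_scheme>\n")
  for (nm in c("SAY", "SAA", "SAW")) {
    p <- x[[nm]]
    cat(sprintf("  %-3s: sM = %g, sF = %g, hM = %g, hF = %g\n",
                nm, p$sM, p$sF, p$hM, p$hF))
  }
  invisible(x)
}

# Epistasis --------------------------------------------------------------

#' Epistasis indicator sigma
#'
#' Male fitness carries a multiplicative term `1 + sigma * epsilon` where
#' the binary indicator sigma depends on the copy numbers at the EPI locus
#' and at its partner SA locus:
#'
#' * `dominance`: sigma = 1 whenever both focal alleles are present in at
#'   least one copy (directional selection on both).
#' * `overdominance`: sigma = 1 only in the double heterozygote
#'   (stabilising selection).
#' * `coadaptation`: sigma = 1 only in the two matched double homozygotes,
#'   `+/+; +/+` and `SA/SA; EPI/EPI` (disruptive selection).
#'
#' @param epi_type One of `"dominance"`, `"overdominance"`,
#'   `"coadaptation"`.
#' @param epi_copies,sa_copies Integer vectors of copy numbers (0, 1 or 2)
#'   at the EPI locus and the partner SA locus; recycled.
#' @return Integer vector of 0/1 indicators.
#' @examples
#' epistasis_sigma("dominance", 1, 2)
#' outer(0:2, 0:2, function(e, s) epistasis_sigma("coadaptation", e, s))
#' @export
epistasis_sigma <- function(epi_type, epi_copies, sa_copies) {
  epi_type <- match.arg(epi_type, c("dominance", "overdominance", "coadaptation"))
  stopifnot(all(epi_copies %in% 0:2), all(sa_copies %in% 0:2))
  n <- max(length(epi_copies), length(sa_copies))
  e <- rep_len(as.integer(epi_copies), n)
  s <- rep_len(as.integer(sa_copies), n)
  out <- switch(epi_type,
    dominance = as.integer(e >= 1L & s >= 1L),
    overdominance = as.integer(e == 1L & s == 1L),
    coadaptation = as.integer((e == 0L & s == 0L) | (e == 2L & s == 2L))
  )
  out
}

#' Epistasis scheme
#'
#' Specifies which SA locus the autosomal EPI locus reads, the interaction
#' type, and the effect size. Epistasis is strictly male-limited: female
#' fitness never includes the epistatic term.
#'
#' @param epi_type Interaction type; see [epistasis_sigma()].
#' @param partner Partner SA locus: `"SAY"`, `"SAA"` or `"SAW"`.
#' @param epsilon Effect size (>= 0); male fitness is multiplied by
#'   `1 + sigma * epsilon`.
#' @return An object of class `epistasis_scheme`.
#' @examples
#' epistasis_scheme("dominance", "SAY", 0.02)
#' @export
epistasis_scheme <- function(epi_type = "dominance", partner = "SAY",
                             epsilon = 0) {
  epi_type <- match.arg(epi_type, c("dominance", "overdominance", "coadaptation"))
  partner <- match.arg(partner, c("SAY", "SAA", "SAW"))
  stopifnot(length(epsilon) == 1L, epsilon >= 0)
  structure(list(epi_type = epi_type, partner = partner, epsilon = epsilon),
            class = "epistasis_scheme")
}

#' @export
print.epistasis_scheme <- function(x, ...) {
  cat(sprintf("<epistasis_scheme> %s, partner %s, epsilon = %g\n",
              x$epi_type, x$partner, x$epsilon))
  invisible(x)
}

#' Viability of a genotype
#'
#' Female fitness is the product of the three SA-locus factors; male
#' fitness is additionally multiplied by `1 + sigma * epsilon`, with sigma
#' from [epistasis_sigma()] evaluated at the EPI locus and its partner SA
#' locus. Fitness depends only on copy numbers, so it is invariant to
#' swapping the maternal and paternal haplotypes.
#'
#' @param maternal,paternal Gamete indices (vectors, recycled).
#' @param sex `"male"` or `"female"` (recycled); typically
#'   `sex_of(maternal, paternal)`.
#' @param scheme A [fitness_scheme()].
#' @param epi An [epistasis_scheme()].
#' @return Numeric vector of positive viabilities.
#' @examples
#' sch <- fitness_scheme(SAY = sa_params(sM = 0.05, sF = -0.05))
#' fitness_of(gamete("SAY"), gamete("Y"), "male", sch,
#'            epistasis_scheme("dominance", "SAY", 0.02))
#' @export
fitness_of <- function(maternal, paternal, sex, scheme, epi) {
  stopifnot(inherits(scheme, "fitness_scheme"), inherits(epi, "epistasis_scheme"))
  n <- max(length(maternal), length(paternal), length(sex))
  am <- gamete_alleles(rep_len(as.integer(maternal), n))
  ap <- gamete_alleles(rep_len(as.integer(paternal), n))
  sex <- rep_len(sex, n)
  copies <- am + ap
  w <- locus_fitness(copies[, "SAY"], sex, scheme$SAY) *
    locus_fitness(copies[, "SAA"], sex, scheme$SAA) *
    locus_fitness(copies[, "SAW"], sex, scheme$SAW)
  sigma <- epistasis_sigma(epi$epi_type, copies[, "EPI"], copies[, epi$partner])
  ifelse(sex == "male", w * (1 + sigma * epi$epsilon), w)
}
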