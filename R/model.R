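# The metabolic model container and its generators.

#' Construct a metabolic model
#'
#' A light S3 container for a constraint-based metabolic model: the
#' stoichiometric matrix \code{S} (metabolites x reactions), flux bounds in
#' mmol/gDW/h, GPR rule strings, exchange flags and an optional biomass
#' reaction.  Reversibility is encoded purely through \code{lb}/\code{ub}.
#'
#' @param mets character vector of metabolite identifiers (unique).
#' @param rxns character vector of reaction identifiers (unique).
#' @param S numeric matrix, \code{length(mets)} x \code{length(rxns)}.
#' @param lb,ub numeric flux bounds per reaction; \code{lb <= ub}.
#' @param gpr character vector of GPR rule strings per reaction
#'   (\code{""} for none).
#' @param biomass_id identifier of the biomass reaction, or \code{NA}.
#' @param formulas optional named character vector of elemental formulas
#'   per metabolite (e.g. \code{c(glc = "C6H12O6")}).
#'
#' @return object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(mets, rxns, S, lb, ub, gpr = NULL,
                            biomass_id = NA_character_, formulas = NULL) {
  S <- as.matrix(S)
  if (is.null(gpr)) gpr <- rep("", length(rxns))
  dimnames(S) <- list(mets, rxns)
  m <- list(mets = as.character(mets), rxns = as.character(rxns),
            S = S, lb = as.numeric(lb), ub = as.numeric(ub),
            gpr = as.character(gpr),
            exchange = detect_exchanges(S),
            biomass_id = biomass_id, formulas = formulas)
  class(m) <- "metabolic_model"
  validate_model(m)
  m
}

# exchange reactions touch exactly one metabolite
detect_exchanges <- function(S) colSums(S != 0) == 1L

validate_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  if (anyDuplicated(m$mets)) stop("duplicate metabolite identifiers")
  if (anyDuplicated(m$rxns)) stop("duplicate reaction identifiers")
  if (nrow(m$S) != length(m$mets) || ncol(m$S) != length(m$rxns))
    stop("S dimensions disagree with identifier lists")
  if (length(m$lb) != length(m$rxns) || length(m$ub) != length(m$rxns))
    stop("bounds length disagrees with reaction count")
  if (any(m$lb > m$ub)) stop("lb > ub for reaction(s): ",
                             paste(m$rxns[m$lb > m$ub], collapse = ", "))
  if (!is.na(m$biomass_id) && !(m$biomass_id %in% m$rxns))
    stop("biomass_id not among reactions")
  for (g in m$gpr) parse_gpr(g)   # raises on malformed rules
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites x %d reactions (%d exchanges%s)\n",
              length(x$mets), length(x$rxns), sum(x$exchange),
              if (!is.na(x$biomass_id)) ", biomass" else ""))
  invisible(x)
}

#' All genes appearing in a model's GPR rules
#' @param model a \code{metabolic_model}.
#' @return character vector of gene identifiers.
#' @export
model_genes <- function(model) {
  unique(unlist(lapply(model$gpr, function(g) gpr_genes(parse_gpr(g)))))
}

#' Simplified glycolysis/TCA toy network
#'
#' A fixed 14-metabolite, 18-reaction model combining a lumped glycolytic
#' chain, a full TCA-like cycle, anaplerotic (PEP carboxylase-like) and
#' malic-enzyme-like reactions, and four exchanges (glucose, pyruvate,
#' succinate, CO2).  Its stoichiometric matrix has rank 14, so the null
#' space is four-dimensional; the sparsest feasible basis contains a
#' glycolysis-like and a TCA-like pathway.  Deterministic: every call
#' returns the identical model.
#'
#' The reference pathway supports are attached as attributes
#' \code{glycolysis_support} and \code{tca_support} (reaction identifier
#' vectors).
#'
#' @return a \code{metabolic_model}.
#' @export
#' @examples
#' toy <- toy_glycolysis_tca()
#' dim(toy$S)        # 14 x 18
toy_glycolysis_tca <- function() {
  mets <- c("glc", "g6p", "f6p", "pep", "pyr", "accoa", "oaa",
            "cit", "icit", "akg", "suc", "fum", "mal", "co2")
  # reaction: list(stoich named vector, lb, ub, gpr)
  rx <- list(
    EX_glc = list(c(glc = -1),                        -10,   1000, ""),
    HEX1   = list(c(glc = -1, g6p = 1),                 0,   1000, "gHEX1"),
    PGI    = list(c(g6p = -1, f6p = 1),             -1000,   1000, "gPGI"),
    EMP    = list(c(f6p = -1, pep = 1),                 0,   1000, "gEMP1 and gEMP2"),
    PYK    = list(c(pep = -1, pyr = 1),                 0,   1000, "gPYK"),
    PDH    = list(c(pyr = -1, accoa = 1, co2 = 1),      0,   1000, "gPDHa and gPDHb and gPDHc"),
    CS     = list(c(accoa = -1, oaa = -1, cit = 1),     0,   1000, "gCS"),
    ACN    = list(c(cit = -1, icit = 1),            -1000,   1000, "gACN"),
    ICDH   = list(c(icit = -1, akg = 1, co2 = 1),       0,   1000, "gICDH"),
    AKGDH  = list(c(akg = -1, suc = 1, co2 = 1),        0,   1000, "gAKGDHa and gAKGDHb"),
    SDH    = list(c(suc = -1, fum = 1),             -1000,   1000, "gSDHa and gSDHb"),
    FUM    = list(c(fum = -1, mal = 1),             -1000,   1000, "gFUM"),
    MDH    = list(c(mal = -1, oaa = 1),             -1000,   1000, "gMDH"),
    PPC    = list(c(pep = -1, co2 = -1, oaa = 1),       0,   1000, "gPPC"),
    ME     = list(c(mal = -1, pyr = 1, co2 = 1),        0,   1000, "gMEa or gMEb"),
    EX_pyr = list(c(pyr = -1),                      -1000,   1000, ""),
    EX_co2 = list(c(co2 = -1),                      -1000,   1000, ""),
    EX_suc = list(c(suc = -1),                      -1000,   1000, "")
  )
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, names(rx)))
  for (j in seq_along(rx)) S[names(rx[[j]][[1]]), j] <- rx[[j]][[1]]
  formulas <- c(glc = "C6H12O6", g6p = "C6H11O9P", f6p = "C6H11O9P",
                pep = "C3H2O6P", pyr = "C3H3O3", accoa = "C2H3O",
                oaa = "C4H2O5", cit = "C6H5O7", icit = "C6H5O7",
                akg = "C5H4O5", suc = "C4H4O4", fum = "C4H2O4",
                mal = "C4H4O5", co2 = "CO2")
  m <- metabolic_model(
    mets, names(rx), S,
    lb = vapply(rx, `[[`, numeric(1), 2),
    ub = vapply(rx, `[[`, numeric(1), 3),
    gpr = vapply(rx, `[[`, character(1), 4),
    formulas = formulas)
  attr(m, "glycolysis_support") <- c("EX_glc", "HEX1", "PGI", "EMP",
                                     "PYK", "EX_pyr")
  attr(m, "tca_support") <- c("EX_pyr", "PDH", "CS", "ACN", "ICDH",
                              "AKGDH", "SDH", "FUM", "MDH", "EX_co2")
  m
}

#' Seeded random consistent metabolic network
#'
#' Generates a model in which every reaction can carry a non-zero
#' steady-state flux.  The construction guarantees consistency: an
#' irreversible backbone chain through all metabolites with an inflow and
#' an outflow exchange, plus random internal shortcut reactions between
#' chain metabolites (each shortcut can reroute the chain flux, and a
#' backward shortcut closes a feasible cycle).  A fraction of reactions is
#' made reversible.  Internal reactions receive synthetic single-gene or
#' isozyme GPRs; metabolites receive small random carbon formulas.
#'
#' @param n_mets number of metabolites (>= 2).
#' @param n_rxns number of reactions (> n_mets).
#' @param rev_fraction fraction of reactions made reversible, in [0, 1].
#' @param seed integer seed; identical seeds give identical models.
#' @return a \code{metabolic_model} with no blocked reactions.
#' @export
random_consistent_model <- function(n_mets, n_rxns, rev_fraction, seed) {
  stopifnot(n_mets >= 2, n_rxns > n_mets,
            rev_fraction >= 0, rev_fraction <= 1)
  rng <- local_rng(seed)
  mets <- sprintf("M%02d", seq_len(n_mets))
  rxn_names <- character(n_rxns)
  S <- matrix(0, n_mets, n_rxns)
  # backbone: EX_in -> M1 -> ... -> Mm -> EX_out
  S[1, 1] <- 1;  rxn_names[1] <- "EX_in"      # -> M1 (uptake positive here)
  for (i in seq_len(n_mets - 1L)) {
    S[i, i + 1L] <- -1; S[i + 1L, i + 1L] <- 1
    rxn_names[i + 1L] <- sprintf("CHN%02d", i)
  }
  S[n_mets, n_mets + 1L] <- -1; rxn_names[n_mets + 1L] <- "EX_out"
  # shortcuts
  n_extra <- n_rxns - n_mets - 1L
  for (k in seq_len(n_extra)) {
    ij <- sample.int(n_mets, 2L)
    coef <- sample(c(1, 1, 2), 2L, replace = TRUE)
    j <- n_mets + 1L + k
    S[ij[1], j] <- -coef[1]; S[ij[2], j] <- coef[2]
    rxn_names[j] <- sprintf("SHC%02d", k)
  }
  rev <- runif(n_rxns) < rev_fraction
  rev[c(1L, n_mets + 1L)] <- TRUE             # exchanges open both ways
  lb <- ifelse(rev, -1000, 0); ub <- rep(1000, n_rxns)
  gpr <- character(n_rxns)
  internal <- which(colSums(S != 0) > 1L)
  for (j in internal) {
    g <- sprintf("g%03d", j)
    u <- runif(1)
    gpr[j] <- if (u < 0.25)                       # enzyme complex
      paste(g, "and", sprintf("g%03db", j))
    else if (u < 0.40)                            # isozymes
      paste(g, "or", sprintf("g%03db", j))
    else g
  }
  formulas <- stats::setNames(sprintf("C%dH%dO%d",
                                      sample(1:6, n_mets, TRUE),
                                      sample(2:12, n_mets, TRUE),
                                      sample(1:6, n_mets, TRUE)), mets)
  rng$restore()
  m <- metabolic_model(mets, rxn_names, S, lb, ub, gpr, formulas = formulas)
  blocked <- blocked_reactions(m)
  if (any(blocked))
    stop("generated model has blocked reactions; increase n_rxns")
  m
}

#' Planted synthetic regulon
#'
#' Draws each transcription factor's regulated gene set from one pathway's
#' gene set, then swaps a \code{noise} fraction of members for random genes
#' from the membership universe.  The planted TF-to-pathway assignment is
#' recorded in the attribute \code{planted} for recovery scoring.
#'
#' @param membership a \code{membership_matrix} (see
#'   \code{\link{pathway_gene_sets}}).
#' @param n_tfs number of TFs to plant (at most the number of pathways).
#' @param noise fraction of each gene set swapped for random genes, in
#'   [0, 1).
#' @param seed integer seed.
#' @return a named list mapping TF identifiers to gene sets (class
#'   \code{regulon}), with attribute \code{planted} (named character:
#'   TF -> pathway id).
#' @export
synthetic_regulon <- function(membership, n_tfs, noise, seed) {
  stopifnot(noise >= 0, noise < 1)
  M <- membership$M
  npw <- ncol(M)
  stopifnot(n_tfs <= npw)
  rng <- local_rng(seed)
  universe <- rownames(M)
  sizes <- colSums(M)
  eligible <- which(sizes >= 2L)
  if (length(eligible) < n_tfs) {
    warning("skipping pathways with < 2 genes; fewer eligible pathways than n_tfs")
    n_tfs <- length(eligible)
  }
  chosen <- sample(eligible, n_tfs)
  reg <- list(); planted <- character(0)
  for (k in seq_len(n_tfs)) {
    pw <- chosen[k]
    genes <- universe[M[, pw] == 1]
    n_swap <- floor(noise * length(genes))
    if (n_swap > 0) {
      out <- sample(seq_along(genes), n_swap)
      pool <- setdiff(universe, genes)
      genes[out] <- sample(pool, n_swap)
      genes <- unique(genes)
    }
    tf <- sprintf("TF%02d", k)
    reg[[tf]] <- genes
    planted[tf] <- colnames(M)[pw]
  }
  rng$restore()
  structure(reg, planted = planted, class = "regulon")
}

# Seed-scoped RNG helper: sets the seed, returns restorer for the old state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}

#' Seeded random modular metabolic network
#'
#' Direct sum of independent consistent sub-networks (blocks), emulating
#' the modular organisation of real metabolism in which nutrient shifts
#' perturb a local subsystem.  Each block is a consistent chain-plus-
#' shortcuts network with its own exchanges and its own gene namespace, so
#' the stoichiometric matrix is block diagonal and pathways never straddle
#' blocks.
#'
#' @param n_blocks number of independent blocks.
#' @param n_mets,n_rxns metabolites and reactions per block.
#' @param rev_fraction fraction of reversible reactions per block.
#' @param seed integer seed.
#' @return a \code{metabolic_model}; block labels in attribute
#'   \code{block} (integer per reaction).
#' @export
random_modular_model <- function(n_blocks, n_mets, n_rxns, rev_fraction,
                                 seed) {
  stopifnot(n_blocks >= 1)
  rng <- local_rng(seed)
  seeds <- sample.int(.Machine$integer.max / 2, n_blocks)
  rng$restore()
  blocks <- lapply(seq_len(n_blocks), function(b)
    random_consistent_model(n_mets, n_rxns, rev_fraction, seeds[b]))
  mets <- unlist(lapply(seq_len(n_blocks), function(b)
    paste0("B", b, "_", blocks[[b]]$mets)))
  rxns <- unlist(lapply(seq_len(n_blocks), function(b)
    paste0("B", b, "_", blocks[[b]]$rxns)))
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  off_m <- 0L; off_r <- 0L
  lb <- ub <- numeric(0); gpr <- character(0); formulas <- character(0)
  block_of <- integer(0)
  for (b in seq_len(n_blocks)) {
    blk <- blocks[[b]]
    m <- length(blk$mets); n <- length(blk$rxns)
    S[off_m + seq_len(m), off_r + seq_len(n)] <- blk$S
    lb <- c(lb, blk$lb); ub <- c(ub, blk$ub)
    g <- blk$gpr
    g[nzchar(g)] <- vapply(g[nzchar(g)], function(s) {
      toks <- gpr_tokenize(s)
      leaf <- !(tolower(toks) %in% c("and", "or")) & !(toks %in% c("(", ")"))
      toks[leaf] <- paste0("B", b, "_", toks[leaf])
      paste(toks, collapse = " ")
    }, character(1))
    gpr <- c(gpr, g)
    formulas <- c(formulas, stats::setNames(blk$formulas,
                                            paste0("B", b, "_", blk$mets)))
    block_of <- c(block_of, rep(b, n))
    off_m <- off_m + m; off_r <- off_r + n
  }
  mm <- metabolic_model(mets, rxns, S, lb, ub, gpr, formulas = formulas)
  attr(mm, "block") <- block_of
  mm
}
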