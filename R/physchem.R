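#' Unsaturation index
#'
#' `Ui = log2(1 + nMB)` with `nMB` the number of multiple bonds; each aromatic
#' bond counts as a multiple bond (benzene contributes 6) and carbonyl/imine
#' double bonds count too.
#'
#' @param g a [molgraph]
#' @return numeric Ui >= 0
#' @export
unsaturation_index <- function(g) {
  nmb <- sum(g$bonds$order >= 2 | g$bonds$aromatic)
  log2(1 + nmb)
}

#' Todeschini hydrophilic factor Hy
#'
#' `Hy = [(1+NHy) log2(1+NHy) + NC (1/A) log2(1/A) + sqrt(NHy/A^2)] / log2(1+A)`
#' with `NHy` the count of hydrophilic-group hydrogens (on O, N, S), `NC` the
#' carbon count and `A` the heavy-atom count. Typically negative for the
#' lipophilic terpenes this package targets.
#'
#' @param g a [molgraph]
#' @return numeric Hy
#' @export
hydrophilic_factor <- function(g) {
  A <- g$n
  NHy <- sum(g$hcount[g$element %in% c("O", "N", "S")])
  NC <- sum(g$element == "C")
  num <- (1 + NHy) * log2(1 + NHy) + NC * (1 / A) * log2(1 / A) + sqrt(NHy / A^2)
  num / log2(1 + A)
}

# Ertl fragment contributions (A^2) for the polar environments in scope
TPSA_CONTRIB <- list(
  O_hydroxyl = 20.23, O_ether = 9.23, O_epoxide = 12.53, O_carbonyl = 17.07,
  o_aromatic = 13.14,
  N_tert = 3.24, NH_sec = 12.03, NH2_prim = 26.02, n_aromatic = 12.89,
  N_double = 12.36, N_triple = 23.79
)

#' Ertl topological polar surface area
#'
#' Sum of published fragment contributions over oxygen and nitrogen
#' environments (hydroxyl 20.23, ether/epoxide 9.23, carbonyl 17.07,
#' aromatic O 13.14; standard amine/aza values for nitrogen).
#'
#' @param g a [molgraph]
#' @return numeric TPSA in square Angstrom
#' @export
tpsa <- function(g) {
  total <- 0
  for (i in seq_len(g$n)) {
    el <- g$element[i]
    if (!el %in% c("O", "N")) next
    deg <- length(neighbours_of(g, i))
    dbl <- sum(g$bonds$order[g$bonds$i == i | g$bonds$j == i] == 2)
    trp <- sum(g$bonds$order[g$bonds$i == i | g$bonds$j == i] == 3)
    contrib <- if (el == "O") {
      if (g$aromatic[i]) TPSA_CONTRIB$o_aromatic
      else if (dbl >= 1) TPSA_CONTRIB$O_carbonyl
      else if (g$hcount[i] >= 1) TPSA_CONTRIB$O_hydroxyl
      else {
        nb <- neighbours_of(g, i)
        in3ring <- length(nb) == 2 &&
          any((g$bonds$i == nb[1] & g$bonds$j == nb[2]) |
              (g$bonds$i == nb[2] & g$bonds$j == nb[1]))
        if (in3ring) TPSA_CONTRIB$O_epoxide else TPSA_CONTRIB$O_ether
      }
    } else {
      if (g$aromatic[i]) TPSA_CONTRIB$n_aromatic
      else if (trp >= 1) TPSA_CONTRIB$N_triple
      else if (dbl >= 1) TPSA_CONTRIB$N_double
      else if (g$hcount[i] == 2) TPSA_CONTRIB$NH2_prim
      else if (g$hcount[i] == 1) TPSA_CONTRIB$NH_sec
      else TPSA_CONTRIB$N_tert
    }
    total <- total + contrib
  }
  total
}

#' Moriguchi octanol-water partition coefficient (MLOGP)
#'
#' The published 13-parameter Moriguchi regression. Terms active for the
#' terpenoid chemotypes: weighted carbon/halogen count `CX^0.6`, N+O count
#' `NO^0.9`, N/O proximity `PRX`, multiple-bond count `UB^0.8` (aromatic bonds
#' per Kekule assignment), aromatic polar substituents `POL`, saturated
#' -hydrocarbon flag `ALK`, non-aromatic ring flag `RNG`, and an intramolecular
#' H-bond flag `HB`. Quaternary-N, nitro, isothiocyanate, amphoteric and
#' beta-lactam terms are structurally zero here and treated as such.
#'
#' @param g a [molgraph]
#' @return numeric MLOGP
#' @export
moriguchi_logp <- function(g) {
  wC <- c(C = 1, F = 0.5, Cl = 1, Br = 1.5, I = 2)
  CX <- sum(wC[g$element], na.rm = TRUE)
  NO <- sum(g$element %in% c("N", "O"))
  # proximity: bonded N/O pair = 2, N/O separated by one atom = 1
  het <- which(g$element %in% c("N", "O"))
  PRX <- 0
  if (length(het) > 1) {
    D <- mol_distance_matrix(g)
    for (a in seq_along(het)) for (b in seq_along(het)) if (a < b) {
      d <- D[het[a], het[b]]
      if (d == 1) PRX <- PRX + 2 else if (d == 2) PRX <- PRX + 1
    }
  }
  UB <- sum(g$bonds$order >= 2)
  # aromatic polar substituent: non-carbon atom or carbonyl carbon attached
  # to an aromatic carbon
  POL <- 0
  for (i in which(g$aromatic & g$element == "C")) {
    for (nb in neighbours_of(g, i)) {
      if (g$aromatic[nb]) next
      if (g$element[nb] != "C") POL <- POL + 1
      else if (any(g$element[double_partners(g, nb)] %in% c("O", "N")))
        POL <- POL + 1
    }
  }
  ALK <- as.integer(all(g$element == "C") && UB == 0)
  RNG <- as.integer(cyclomatic_number(g) > sum_aromatic_rings(g))
  # intramolecular H bond: OH ortho to another O/N substituent on a ring
  HB <- 0L
  oh <- which(g$element == "O" & g$hcount == 1)
  if (length(oh) > 0 && NO > 1) {
    D <- mol_distance_matrix(g)
    other <- setdiff(which(g$element %in% c("N", "O")), oh)
    for (o1 in oh) if (length(other) > 0 && any(D[o1, other] <= 3)) HB <- 1L
  }
  1.244 * CX^0.6 - 1.017 * NO^0.9 + 0.406 * PRX - 0.145 * UB^0.8 +
    0.511 * HB + 0.268 * POL + 0.912 * ALK - 0.392 * RNG - 1.041
}

# number of aromatic 6-rings (cyclomatic contribution of aromatic systems)
sum_aromatic_rings <- function(g) {
  ab <- sum(g$bonds$aromatic)
  if (ab == 0) return(0L)
  # each isolated benzene ring contributes 6 aromatic bonds and 1 cycle
  as.integer(round(ab / 6))
}

# Wildman-Crippen (1999) published atomic contributions for the C/H/O types
# occurring in terpene/terpenoid/phenylpropanoid chemotypes.
WC_PARAMS <- list(
  C1  = c(logp =  0.1441, mr = 2.503),  # sp3 CH3/CH2, C/H neighbours only
  C2  = c(logp =  0.0000, mr = 2.433),  # sp3 CH/C, C/H neighbours only
  C3  = c(logp = -0.2035, mr = 2.753),  # sp3 CH3/CH2 bonded to N/O
  C4  = c(logp = -0.2051, mr = 2.731),  # sp3 CH/C bonded to N/O
  C5  = c(logp = -0.2783, mr = 5.007),  # C double-bonded to heteroatom
  C6  = c(logp =  0.1551, mr = 3.513),  # sp2 C in C=C
  C8  = c(logp =  0.0845, mr = 2.464),  # sp3 CH3 on aromatic ring
  C10 = c(logp = -0.0516, mr = 2.488),  # sp3 CH2 on aromatic ring
  C11 = c(logp =  0.1193, mr = 2.582),  # sp3 CH on aromatic ring
  C12 = c(logp = -0.0967, mr = 2.576),  # sp3 C on aromatic ring
  C18 = c(logp =  0.1581, mr = 3.350),  # aromatic CH
  C21 = c(logp =  0.1360, mr = 3.509),  # aromatic C bonded to aliphatic C
  C22 = c(logp =  0.4619, mr = 4.067),  # aromatic C bonded to N
  C23 = c(logp =  0.5437, mr = 3.853),  # aromatic C bonded to O
  O1  = c(logp =  0.1552, mr = 1.080),  # aromatic O
  O2  = c(logp = -0.2893, mr = 0.8238), # alcohol / phenol O
  O3  = c(logp = -0.0684, mr = 1.085),  # aliphatic ether O
  O4  = c(logp = -0.4195, mr = 1.182),  # aromatic-attached ether O
  O9  = c(logp = -0.1526, mr = 0.000),  # carbonyl O
  H1  = c(logp =  0.1230, mr = 1.057),  # H on carbon
  H2  = c(logp = -0.2677, mr = 1.395),  # H on hydroxyl O
  H3  = c(logp =  0.2142, mr = 0.9627)  # H on nitrogen
)

wc_atom_type <- function(g, i, hyb) {
  el <- g$element[i]
  nb <- neighbours_of(g, i)
  if (el == "C") {
    if (g$aromatic[i]) {
      side <- nb[!g$aromatic[nb]]
      if (length(side) == 0) return("C18")
      sel <- g$element[side]
      if (any(sel == "O")) return("C23")
      if (any(sel == "N")) return("C22")
      return("C21")
    }
    if (hyb[i] %in% c("sp2", "sp")) {
      dp <- double_partners(g, i)
      if (any(g$element[dp] != "C")) return("C5")
      return("C6")
    }
    # sp3
    if (any(g$element[nb] %in% c("N", "O")))
      return(if (g$hcount[i] >= 2) "C3" else "C4")
    if (any(g$aromatic[nb])) {
      return(switch(as.character(min(g$hcount[i], 3)),
                    "3" = "C8", "2" = "C10", "1" = "C11", "0" = "C12"))
    }
    return(if (g$hcount[i] >= 2) "C1" else "C2")
  }
  if (el == "O") {
    if (g$aromatic[i]) return("O1")
    dbl <- double_partners(g, i)
    if (length(dbl) > 0) return("O9")
    if (g$hcount[i] >= 1) return("O2")
    if (any(g$aromatic[nb])) return("O4")
    return("O3")
  }
  stop("no Wildman-Crippen contribution for atom environment: atom ", i,
       " (", el, ")")
}

#' Wildman-Crippen AlogP and molar refractivity (AMR)
#'
#' Atomic-contribution estimates of the octanol-water partition coefficient
#' and molar refractivity, using the published Wildman-Crippen values for the
#' C/H/O atom types present in this chemical space. Note the printed reference
#' tables used the older Ghose-Crippen-Viswanadhan parameterisation, so AlogP
#' deviates systematically by a few tenths; AMR agrees closely.
#'
#' @param g a [molgraph]
#' @return named numeric vector `c(AlogP, AMR)`
#' @export
ghose_crippen <- function(g) {
  hyb <- hybridization(g)
  logp <- 0; mr <- 0
  for (i in seq_len(g$n)) {
    ty <- wc_atom_type(g, i, hyb)
    p <- WC_PARAMS[[ty]]
    logp <- logp + p["logp"]; mr <- mr + p["mr"]
    if (g$hcount[i] > 0) {
      hty <- if (g$element[i] == "O") "H2" else if (g$element[i] == "N") "H3" else "H1"
      hp <- WC_PARAMS[[hty]]
      logp <- logp + g$hcount[i] * hp["logp"]
      mr <- mr + g$hcount[i] * hp["mr"]
    }
  }
  c(AlogP = unname(logp), AMR = unname(mr))
}

#' Aggregate charge descriptors from an external atomic-charge vector
#'
#' Pure aggregation: `Qpos = sum of positive charges`, `Qneg = sum of negative
#' charges`, `Qtot = sum |q_i| = Qpos - Qneg`. Charges come from any external
#' charge model (the reference values derive from DFT runs); the package never
#' computes quantum-chemical charges.
#'
#' @param q numeric vector of per-atom partial charges
#' @return named numeric vector `c(Qpos, Qneg, Qtot)`
#' @export
charge_descriptors <- function(q) {
  if (length(q) == 0 || !is.numeric(q)) stop("charge vector must be non-empty numeric")
  c(Qpos = sum(pmax(q, 0)), Qneg = sum(pmin(q, 0)), Qtot = sum(abs(q)))
}

#' Physicochemical descriptor profile
#'
#' Ui, Hy, AMR, TPSA, MlogP, AlogP computed from the graph, plus Qpos/Qneg/
#' Qtot when an external charge vector is supplied (NA otherwise).
#'
#' @param g a [molgraph]
#' @param charges optional numeric per-atom charge vector
#' @return named numeric vector
#' @export
physchem_profile <- function(g, charges = NULL) {
  gc <- ghose_crippen(g)
  qd <- if (is.null(charges)) c(Qpos = NA_real_, Qneg = NA_real_, Qtot = NA_real_)
        else charge_descriptors(charges)
  c(qd,
    Ui = unsaturation_index(g),
    Hy = hydrophilic_factor(g),
    AMR = unname(gc["AMR"]),
    TPSA = tpsa(g),
    MlogP = moriguchi_logp(g),
    AlogP = unname(gc["AlogP"]))
}
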