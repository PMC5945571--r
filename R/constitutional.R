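# helpers over the bond table ------------------------------------------------

neighbours_of <- function(g, i) {
  sel <- g$bonds$i == i | g$bonds$j == i
  ifelse(g$bonds$i[sel] == i, g$bonds$j[sel], g$bonds$i[sel])
}

# indices of atoms double-bonded to atom i (non-aromatic bonds only)
double_partners <- function(g, i) {
  sel <- (g$bonds$i == i | g$bonds$j == i) & g$bonds$order == 2 & !g$bonds$aromatic
  ifelse(g$bonds$i[sel] == i, g$bonds$j[sel], g$bonds$i[sel])
}

has_multiple_bond <- function(g, i) {
  sel <- g$bonds$i == i | g$bonds$j == i
  any(g$bonds$order[sel] >= 2 & !g$bonds$aromatic[sel]) || g$aromatic[i]
}

#' Constitutional (functional-group count) descriptors
#'
#' Counts per the structural-descriptor table conventions:
#' \describe{
#'   \item{nCs / nCt}{sp3 carbons with exactly 2 / 3 carbon neighbours
#'     (classic secondary/tertiary definition: a carbinol CH(OH) with two C
#'     neighbours is secondary)}
#'   \item{nCconj}{non-aromatic sp2 carbons (including carbonyl carbons)
#'     whose multiple-bond unit is conjugated across one single bond with
#'     another multiple bond or an aromatic ring; aromatic carbons themselves
#'     are excluded}
#'   \item{nRdCp / nRdCs / nRdCt}{aliphatic C=C carbons with 1 / 2 / 3 heavy
#'     neighbours (terminal methylene, =CH-, =C<)}
#'   \item{nRCO}{aliphatic (non-aromatic, non-aldehyde) ketone carbonyls}
#'   \item{nArOH}{hydroxyls on aromatic carbon (phenols)}
#'   \item{nOH}{non-phenolic hydroxyls}
#'   \item{nHDon}{H-bond donor hydrogens (OH + NH)}
#'   \item{nHAcc}{H-bond acceptor atoms (N + O)}
#' }
#'
#' @param g a [molgraph]
#' @return named integer vector of the 11 counts
#' @export
constitutional_counts <- function(g) {
  hyb <- hybridization(g)
  deg <- degrees(g)
  isC <- g$element == "C"
  isO <- g$element == "O"

  ncarbon <- vapply(seq_len(g$n), function(i)
    sum(g$element[neighbours_of(g, i)] == "C"), integer(1))
  nCs <- sum(isC & hyb == "sp3" & ncarbon == 2)
  nCt <- sum(isC & hyb == "sp3" & ncarbon == 3)

  # aliphatic C=C carbons
  in_cc <- vapply(seq_len(g$n), function(i) {
    isC[i] && !g$aromatic[i] && any(g$element[double_partners(g, i)] == "C")
  }, logical(1))
  nRdCp <- sum(in_cc & deg == 1)
  nRdCs <- sum(in_cc & deg == 2)
  nRdCt <- sum(in_cc & deg == 3)

  # conjugation: a non-aromatic sp2 carbon (C=C or C=O) whose multiple-bond
  # unit is single-bonded to an atom that is aromatic or carries another
  # non-aromatic multiple bond
  sp2c <- vapply(seq_len(g$n), function(i) {
    isC[i] && !g$aromatic[i] && length(double_partners(g, i)) > 0
  }, logical(1))
  conj <- vapply(seq_len(g$n), function(i) {
    if (!sp2c[i]) return(FALSE)
    unit <- c(i, double_partners(g, i))
    for (u in unit[g$element[unit] == "C"]) {
      for (nb in setdiff(neighbours_of(g, u), unit)) {
        if (g$aromatic[nb] || length(double_partners(g, nb)) > 0) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  nCconj <- sum(conj)

  # carbonyls
  carbonyl_c <- which(isC & vapply(seq_len(g$n), function(i)
    any(g$element[double_partners(g, i)] == "O"), logical(1)))
  nRCO <- sum(vapply(carbonyl_c, function(i) {
    !g$aromatic[i] && g$hcount[i] == 0 &&
      sum(g$element[neighbours_of(g, i)] == "C") == 2
  }, logical(1)))

  # hydroxyls
  oh <- which(isO & g$hcount == 1 & deg == 1)
  aroh <- sum(vapply(oh, function(i) g$aromatic[neighbours_of(g, i)], logical(1)))
  noh <- length(oh) - aroh

  nh <- sum(g$hcount[g$element == "N"])
  nHDon <- length(oh) + sum(g$element == "N" & g$hcount > 0)
  nHAcc <- sum(g$element %in% c("N", "O"))

  c(nCs = nCs, nCt = nCt, nCconj = nCconj,
    `nR=Cp` = nRdCp, `nR=Cs` = nRdCs, `nR=Ct` = nRdCt,
    nRCO = nRCO, nArOH = aroh, nOH = noh,
    nHDon = nHDon, nHAcc = nHAcc)
}
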