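---
title: "Collagen palaeoproteomic phylogenetics: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collagen palaeoproteomic phylogenetics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bone collagen (I) outlives ancient DNA by an order of magnitude, so for many
extinct vertebrates the only recoverable molecular characters are collagen
peptides observed by mass spectrometry. The analytical chain is long: the
two chains of the triple helix (alpha1(I), alpha2(I), each an uninterrupted
Gly-Xaa-Yaa repeat of roughly 1000 residues) are digested with trypsin; the
digest is surveyed as a MALDI peptide mass fingerprint (PMF); selected
precursors are fragmented and their b/y ion ladders matched against a
protein database; accepted peptide-spectrum matches (PSMs) are assembled
into a partial sequence for the fossil; and the concatenated
alpha1+alpha2 alignment is analysed by maximum likelihood and by split
networks. `CollagenPhylo` implements that chain end to end, together with a
seeded simulator of every data type it consumes, so each stage — and the
whole — can be tested quantitatively without instrument data.

## Mass arithmetic and digestion

All masses are monoisotopic. Residue masses are embedded constants computed
from standard atomic masses; a peptide's neutral mass is the residue sum
plus water (18.010565 Da) and MH+ adds one proton (1.007276 Da). MALDI
spectra are treated as singly charged throughout; multiple charge states
are out of scope.

Trypsin is modelled by the Keil rule: cleavage C-terminal to K or R except
before P. `trypticDigest()` returns every peptide with up to `maxMissed`
(default 2) internal missed cleavages, with 1-based coordinates on the
parent chain. The zero-missed peptides tile the chain exactly — a property
the tests exploit as an oracle.

Variable modifications are the shipped set used in degraded-collagen work:
oxidation/hydroxylation (+15.99491 Da on P, K, M — hydroxyproline is always
represented as P plus this modification, never as a 21st letter),
deamidation (+0.98402 Da on N, Q) and N-terminal pyroglutamate from Q
(−17.02655) or E (−18.01056). `applyModifications()` enumerates every
assignment of at most `maxVariable` (default 2) modification *instances* to
allowed sites, no site carrying two. A note on that cap: search engines
often cap the number of variable modification *types* rather than
instances; this package deliberately caps instances, which is the stricter
reading, and the simulator's hydroxylation rate is moderate enough
(below) that most peptides carry at most two.

One positional restriction matters for accuracy: in database construction,
proline oxidation is enumerated only at Yaa-frame positions
(`proOxYaaOnly`, default on), because prolyl 4-hydroxylase acts on the Yaa
proline of the Gly-Xaa-Yaa repeat. Without it, a Yaa-independent
hydroxyproline variant (+15.995 Da) shadows genuine P→I/L substitutions
(+16.031 Da) at Xaa sites — indistinguishable at the 0.5 Da tolerance — and
corrupts downstream residue calls.

## Ion scoring and database search

The scorer is an explicit stand-in for the undisclosed commercial scorer
whose acceptance filter (ion score > 40) is the field's convention. For a
spectrum with $m$ peaks spanning $s$ Da and a candidate with $n$
theoretical singly charged b/y fragments, each fragment independently hits
a peak with probability $p = \min(1, 2m\,\mathrm{tol}/s)$ under a
uniform-peak null; with $k$ fragments matched within the tolerance
(default 0.5 Da, as for the precursor), the ion score is
$-10\log_{10} \Pr[\mathrm{Bin}(n,p) \ge k]$, truncated at zero. Acceptance
at 40 bounds the per-spectrum random-match probability by $10^{-4}$ under
that null, which the test suite verifies empirically on 10,000 null-model
decoys. The null is deliberately simple; on highly repetitive collagen
sequence it is anti-conservative (fragment masses cluster), which is one
reason residue calls carry an extra validation layer (below).

`searchSpectra()` implements two passes. The normal pass considers database
variants whose MH+ lies within the precursor tolerance and keeps the
best-scoring one per spectrum (no chimeric spectra). The error-tolerant
pass, for spectra the normal pass left unassigned, considers candidates
whose precursor differs by some $\Delta$ up to 80 Da and places the single
unanticipated shift $\Delta$ at each residue in turn, keeping the placement
that maximises the matched-fragment count (ties resolve to the most
N-terminal position, mirroring one-event error-tolerant semantics). This
pass is what discovers fossil-specific substitutions absent from the
database; the suite verifies that an A→T (+30.01057 Da) substitution is
found and localised exactly when the flanking fragments are present.

## From PSMs to sequence: the validation layer

`mapPsmsToSites()` converts accepted PSMs into per-site residue calls with
two rules that play the role of the manual spectrum validation practised in
this field:

* **Ladder support.** A residue is called only when it is delimited by
  matched fragment ions — both flanking b ions or both flanking y ions
  (peptide termini and the precursor count as matched boundaries). A
  mass-coincident but wrong peptide can exceed score 40 on repetitive
  collagen; its unsupported residues are simply never called.
* **Deamidation ambiguity.** Deamidated N/Q is *exactly* isobaric with
  D/E, so a call at a deamidated site would be unverifiable from the
  spectrum; such sites stay unobserved by default
  (`deamidatedAs = "unknown"`).

Error-tolerant shifts convert to residue calls only when the shifted mass
matches a standard residue within 0.01 Da (smaller than the 0.036 Da K/Q
gap); the I/L ambiguity resolves provisionally to L. Conflicting calls at a
site go to the higher ion score, with exact ties left unobserved.

Two fill modes exist because the workflow uses partial sequences twice with
different risk profiles: the *search database* fills unknown stretches with
the column-majority consensus of the reference taxa (standard practice
when the species of interest lacks a reference sequence), while the *phylogenetic alignment* codes them as missing ('?') so
that consensus signal cannot leak into tree inference. Because a
consensus-filled alignment would pull the fossil towards the majority
signal, both modes are provided and `fillMode = "unknown"` is the default for
phylogenetics.

Isobaric I/L cannot be distinguished by mass at all: before analysis every
alignment column containing I or L is rewritten to the column's most
frequent member (ties to the alphabetically first, reported), which
canonicalises without changing column mass content.

## Phylogenetics

The inference model is Dayhoff with discrete-gamma rate heterogeneity
(4 equal-probability categories using category means) and an optional fixed
proportion of invariable sites (default 0 — there is no canonical value
for such data, so the parameter is exposed but not guessed).
Exchangeabilities and frequencies are embedded from the canonical published
matrix. The numerical engines are `phangorn` and `ape` — the role such workflows
delegate to dedicated programs like PhyML and SplitsTree — behind a surface that
adds input checking and degenerate-case policy:

* ML pairwise distances use flat partial likelihoods at unobserved sites
  (equivalent to pairwise deletion); zero shared sites is an error naming
  the pair; saturated estimates are capped (default 5 subst./site) with a
  warning, never silently.
* Neighbor joining clamps negative branch estimates to zero, transferring
  the deficit to the adjacent branch.
* The ML search starts from the NJ tree and alternates branch-length
  optimisation with NNI hill-climbing; at the scale of these data
  (≤ 37 taxa) NNI is adequate and SPR is not implemented.
* Bootstrap supports are column-resampling percentages over re-searched
  replicates; production analyses use on the order of 10,000 replicates,
  while desk-scale runs here default to 100. Alignments without a single
  parsimony-informative site yield supports flagged degenerate.
* NeighborNet estimates non-negative circular split weights; splits below
  1e-6 are dropped. On a tree metric the output equals the tree's splits
  (a tested property); on conflicting signal it shows boxes.
* Rooting (for display and monophyly queries) is by outgroup only; all
  computation is on unrooted trees.

The exhaustive-state likelihood oracle in the test suite verifies the
pruning likelihood to 1e-10 on 4-taxon cases, including the gamma
averaging, and re-rooting invariance is checked directly.

## The simulator: what it emulates and what it does not

`simulationConfig()` defaults encode the emulated study conditions:

| Parameter | Default | Rationale |
|---|---|---|
| chain lengths | 1014 + 1014 | ~1000-residue triple-helical domains |
| tree | 11 taxa | fossil sister to a tenrec analogue inside an afrotherian-like clade, plus xenarthran/pangolin analogues and a distant outgroup; branch lengths at the few-percent scale of mammalian collagen divergence |
| Xaa/Yaa composition | Dayhoff equilibrium, P at 0.30, K+R at 0.13 | proline-rich repeat; K+R ≈ 8.7% of residues as in real alpha chains, setting realistic tryptic fragment lengths |
| glycine template | invariant | the repeat is structurally obligatory |
| target coverage | 0.75 | typical unconstrained coverage of degraded collagen; the >40 score filter then reduces called sites to roughly half, reproducing the published coverage narrative |
| hydroxylation rate | 0.3 per Yaa-proline | real spectra show site-specific hydroxylation but no canonical rate exists; chosen so most peptides carry ≤ 2 modification instances |
| PMF noise | 0.05 Da jitter, 50 decoy peaks | sub-tolerance mass accuracy plus chemical noise |
| MS/MS | dropout 0.1, 30 noise peaks, 0.05 Da jitter; summed fragment intensity 3000–5000 counts | the quoted fragment ion-count scale; intensities otherwise arbitrary units |
| precursor window | 800–3500 Da | precursors are selected from the MALDI PMF window |

Degradation removes whole tryptic peptides (contiguous blocks drawn at
random until the target is reached), because fossil coverage loss operates
peptide-wise through score filtering, not residue-wise. The realised
retention equals the non-'?' fraction exactly, and is reported.

Every generator is bit-reproducible given its seed and restores the
caller's RNG state. The pipeline derives per-stage substreams from one root
seed, so a run configuration determines every output byte (a tested
property).

What the simulator does **not** emulate: chromatography and retention
time, isotope envelopes (monoisotopic sticks only), multiply charged ESI
species, deamidation as a diagenetic process (deamidation exists only as a
search-side modification), correlated noise, and instrument-specific
intensity response. Passing tests therefore demonstrate the pipeline's
correctness under idealised MALDI-like data with Gaussian mass error and
uniform decoys — not robustness to every artefact of real LC-MS runs.

## Problem sizes and numerical choices

Desk-scale defaults were chosen so the full test suite and the acceptance
script run comfortably on one CPU: unit tests use chains of 90–300
residues; the end-to-end recovery experiment uses 20 replicates of
501+501-residue chains with 100 bootstrap replicates each; the acceptance
script runs one full 1014+1014 analysis plus a 10-replicate recovery sweep.
Smaller chains carry *less* phylogenetic signal, so desk scale is the
conservative direction for recovery claims.

Numerical details worth knowing: transition matrices come from the spectral
decomposition of the reversible rate matrix (exact to ~1e-14 against an
independent matrix exponential); peak matching is greedy on |Δm/z|, which
equals optimal matching whenever peak spacing exceeds twice the tolerance
(the collagen PMF regime — note that a peak 0.2 Da from a reference beats
one 0.4 Da away, wherever they sit); PMF similarity is a matched-peak Dice
score, a quantitative stand-in for what is visually compared in practice;
biomarker grouping bins sorted masses with a gap rule at the tolerance.

## Known limitations

* Peptides differing from every database sequence at two or more sites are
  uninterpretable under one-event error-tolerant semantics; even noiseless
  runs therefore call only part of the fossil chain (the called part is
  exact — a tested invariant). Real workflows mitigate this with manually
  curated species sequences in the database.
* The binomial score null ignores fragment-mass clustering in repetitive
  sequence; the ladder-support rule compensates at the residue level, but
  per-spectrum scores on collagen should not be interpreted as calibrated
  p-values.
* Site calls carry no explicit model of deamidation-driven sequence decay;
  the default simply refuses to call those sites.
* The master coordinate system is fixed input; no multiple sequence
  alignment is computed, and indels are out of scope (collagen helices are
  length-conserved at this evolutionary depth).
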