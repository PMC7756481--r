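---
title: "Phenotype-driven variant prioritization: models, parameters and design choices"
author: "PhenoVarRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven variant prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhenoVarRank)
```

# Overview

`PhenoVarRank` automates the three steps of exome-based rare-disease
diagnosis that are mechanical enough to be automated: variant filtration,
ACMG classification with a Bayesian posterior, and phenotype similarity
scoring between the patient and each candidate disease. The output is a
ranked shortlist of disease–variant pairs for manual curation, not a
diagnosis; every design choice below reflects that division of labour.

# The similarity model

## Definition

Patient and disease phenotypes are sets of terms in a rooted `is_a` DAG
(the Human Phenotype Ontology, or a structurally similar toy ontology).
For one patient symptom $p$ compared against a disease's symptom set $S_d$,
each pair $(p, s)$, $s \in S_d$, contributes a *weight candidate*: the
maximal depth of a common ancestor of $p$ and $s$. The weight of $p$ is the
maximum candidate, normalised by $p$'s own depth:

$$ w(p, S_d) \;=\; \frac{\max_{s \in S_d} \operatorname{depth}(\mathrm{MCA}(p, s))}{\operatorname{depth}(p)} \in [0, 1]. $$

Averaging $w(\cdot, S_d)$ over the patient set gives $S_1$; symmetrically,
averaging disease-term weights against the patient set gives $S_2$; the
reported score is $10\,(S_1 + S_2)/2 \in [0, 10]$.

Depth, not information content, carries the specificity signal: common
ancestors deep in the ontology indicate that two symptoms agree on a
specific clinical finding, while agreement only near the root is
uninformative. This makes the score independent of any symptom–disease
frequency corpus.

## Two conventions the definition does not fix

Both are fixed here deliberately and consistently:

* **Depth is the longest path from the root.** In a DAG with
  multi-parent terms, longest-path depth reflects the most specific
  placement of a term and maximises the discriminative range of MCA
  depths. `termDepth()` computes it once for all terms in topological
  order at graph construction.
* **A term is its own ancestor.** Without this, $\mathrm{MCA}(p,p)$ would
  sit strictly above $p$ and identical symptom pairs would not reach
  weight 1 — and identical sets would not reach the printed maximum of 10.
  With it, `similarityScore(S, S) == 10` exactly, for any set of non-root
  terms, on any ontology.

## Normalisation

The 0–10 range is part of the score's published interface, but the scaling
from raw MCA depths to that range is not. We divide each raw weight by
$\operatorname{depth}(p)$ *per source term* before averaging, then multiply
the two-direction mean by 10. This choice (a) guarantees the printed range
on any ontology, regardless of its maximum depth, (b) makes identical sets
score exactly 10 and root-only-overlap sets exactly 0, and (c) treats a
shallow recorded term fairly: a parent-level term can still fully cover a
more specific disease term in the $S_1$ direction, while the $S_2$
direction records the loss of specificity. Because the production scaling
of the original system is not recoverable, downstream thresholds on the
score (notably the PP4 threshold of 5) are configuration values, not
reproducible boundaries.

The directed average is written over the source set's terms against the
*target* set ($w(p, S_d)$ inside the $S_1$ sum); this is the only reading
under which "each patient symptom is compared with each disease symptom"
and the two directions differ.

# The ACMG engine

## Rules

`evaluateRules()` fires the subset of ACMG/AMP criteria computable from
the modelled annotations: BA1 (> 5% in any population source), PVS1 (null
consequence in a loss-of-function disease gene), PS1/PM5 (same amino-acid
change/residue as a known pathogenic variant), PM1 (missense in a
hotspot), PM2 (absent or rare in controls), PM4 (protein-length change),
PP2 (missense in a constrained gene), PP3/BP4 (in-silico consensus at the
0.5 cutoff, missense tools for missense and splice tools for splice-region
consequences), BS1 (above the disease's maximum credible frequency), BP7
(synonymous without predicted splice impact). Rules needing unmodelled
data — functional assays (PS3), segregation LOD scores (PP1), case-control
counts (PS4) — are intentionally absent, and the rule enumeration is
closed.

Missing data are explicit: a variant with no frequency entry is *absent
from controls* (fires PM2), which is different from an observed frequency
of zero in a queried source; in-silico scores are never zero-filled, and
PP3/BP4 only consult the scores applicable to the consequence class.

## The Bayesian combiner

Evidence items multiply odds of pathogenicity exponentially:
$\mathrm{odds} = O_{PVS}^{\,e}$ with $e$ the sum of exponents 1, 1/2, 1/4,
1/8 (very strong/strong/moderate/supporting; benign items subtract), and

$$ \Pr(\text{pathogenic}) = \frac{\mathrm{odds} \cdot \pi}{(\mathrm{odds} - 1)\pi + 1}. $$

Defaults $\pi = 0.10$ and $O_{PVS} = 350$ are the canonical constants of
the points-based Bayesian reformulation of the ACMG system; they are
exposed in `bayesConfig()` rather than hard-coded. With no evidence the
posterior equals the prior; BA1 is stand-alone and short-circuits the
posterior to 0 regardless of other items. Class boundaries are
$\geq 0.99$ P, $\geq 0.90$ LP, $> 0.10$ VUS, $> 0.001$ LB, else B —
inclusive on the pathogenic side and inclusive-downward on the benign
side, so every boundary value has a deterministic class.

## Evidence updates

PP4 (phenotype specificity, supporting) fires when the candidate's
similarity score reaches the threshold (default 5 — the level above which
confirmation of a candidate was observed to be markedly more likely) *and*
the disease–gene pair is the only candidate explanation reaching that
threshold for the patient. The uniqueness gate is our reading of
"phenotype specific": a phenotype compatible with several candidate
diseases is specific evidence for none of them. Both the threshold and
the gate are configuration (`pp4_threshold`, `pp4_require_unique`).

Family testing maps to evidence operations: absence in both parents gives
PS2 with confirmed parentage and PM6 without; recessive candidates in
trans gain PM3, in cis gain BP2 and are flagged rejected; a
high-penetrance dominant variant transmitted by an unaffected parent gains
BS4 and is rejected. Rejection flags the row rather than deleting it: the
curator sees why a candidate fell.

# The funnel and ranking

Stages run in a fixed order: frequency filter → gene–disease matching →
classification → low-impact exclusion (classes B/LB, and non-coding
consequences unless a splice score rescues them at ≥ 0.5) → inheritance
filter → similarity scoring → tier assignment → PP4 → family evidence →
ranking. Classification precedes the impact filter because that filter
consumes the class; VUS are deliberately retained, as they are the
candidates that family testing most often resolves.

Numerical conventions: all three tier thresholds (0.9, 0.499, 0.1) and
the BA1 cutoff compare with strict greater-than, per their "above"
phrasing; a candidate at posterior exactly 0.1 is dropped (but counted in
the funnel log). The sort key is (tier ascending, similarity descending,
posterior descending, gene, disease, variant key), which makes reports
byte-identical across runs. Inheritance handling: dominant diseases keep
any zygosity; recessive keep homozygotes, or two or more heterozygotes in
the same gene flagged `phase_unknown` until family testing; X-linked keep
hemizygous and homozygous calls, with heterozygous female carriers behind
the `xl_keep_het_female` flag (default off) since the evidence for
retaining them is disease-specific.

The funnel log counts *distinct variants* entering and leaving each stage
(plus candidate-pair counts where fan-out applies), so its counts are
non-increasing even when one variant matches several diseases.

# What the synthetic fixtures emulate

`fixtureConfig()` defaults define the study conditions; they were chosen
once, from the structure the pipeline assumes, and are not tuned per test:

* **Ontology** (`depth = 8`, `branching = 3`, `extra_parent_prob = 0.1`):
  ~9.8k terms, comparable in depth to clinical phenotype ontologies, with
  occasional multi-parent terms so longest-path depth actually differs
  from shortest-path.
* **Knowledge base** (200 genes, 150 diseases, 4–8 deep terms each):
  inheritance sampled AD 70% / AR 24% / XL 6%, the mix reported for
  confirmed diagnoses in rare-disease cohorts; mechanisms LoF 60% /
  GoF 20% / unknown 20%; maximum credible allele frequencies 2e-4
  (dominant/X-linked) and 2e-3 (recessive).
* **Patient** (5 true terms, 20% parent-swap, 2 noise terms): parent
  swapping emulates clinicians recording a less specific ancestor term;
  noise terms emulate incidental findings. Swapping leaves $S_1$ at 1
  (an ancestor still covers the disease term) but lowers $S_2$ — the
  asymmetry the normalisation is designed to expose.
* **Exome** (500 background variants, 90% common): the two-component
  frequency mixture (common uniform on (0.05, 0.5], rare log-uniform
  1e-6–1e-3 or absent) is the simplest spectrum that exercises the
  BA1/BS1/PM2 boundaries and lets the frequency filter remove the bulk of
  variants, as it does on real exomes. The spiked causal variant is
  consistent with the disease's mechanism and inheritance (stop-gained for
  LoF; hotspot missense matching a known pathogenic change otherwise;
  het/hom/hemi per AD/AR/XL — recessive cases are spiked homozygous, the
  simpler of the two recessive configurations, with compound-heterozygous
  logic exercised separately in the inheritance-filter and family-evidence
  tests).

What the fixtures do **not** model: realistic human allele-frequency
spectra, linkage between variants, annotation errors, multi-gene
phenotypes, term frequency (information content) structure in the
ontology, and the sheer scale of a real exome (~10^5 variants). Passing
the spike-in recovery test therefore demonstrates that the pipeline's
logic recovers a well-supported causal variant against a background of
plausible distractors — not a clinical diagnostic yield.

One master seed fans out to fixed per-generator child seeds, so the same
ontology appears regardless of exome size, and every generated file is
byte-identical across reruns of the same configuration.

# Problem sizes and numerical tolerances in the test suite

Exact algebraic identities (worked toy-ontology scores, the closed-form
posterior) are asserted to 1e-9–1e-12. The oracle-equivalence suite runs
1,000 random DAGs (5–60 terms) against brute-force ancestor enumeration
and 500 full-scorer instances against a naive double loop. Spike-in
recovery uses 100 seeded default fixtures and requires the causal variant
at rank 1 in ≥ 90% of them and in the top 5 in ≥ 99%; the staged
reclassification check (baseline → +PP4 → +family evidence) uses 15
simulated cases and asserts a non-decreasing P+LP fraction. These sizes
were chosen to give stable pass/fail behaviour at desk scale.

# Known limitations

* The score-to-0–10 scaling is a reconstruction; absolute score values are
  not comparable with the original production system, so score thresholds
  should be recalibrated before clinical use.
* PM2/BS1 frequency cutoffs and the tier/posterior interaction are
  configuration, not published constants.
* Compound-heterozygous candidates are kept with unknown phase until a
  segregation record arrives; no statistical phasing is attempted.
* No CNV/UPD, mitochondrial, somatic or incidental-finding handling; the
  pipeline assumes a single affected proband with optional parental data.
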