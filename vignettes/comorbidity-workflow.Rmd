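---
title: "Comorbid phenotype networks from CNV cohorts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbid phenotype networks from CNV cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cohorts of patients with rare genomic disorders — ontology-coded phenotype
profiles plus copy-number variants (CNVs) — are too heterogeneous for
per-disease analysis: most patients are undiagnosed and their profiles
overlap only partially with known diseases. comorbidNet decomposes such
profiles into individual phenotypes and asks three questions:

1. Which phenotype **pairs** co-occur across patients more often than chance
   (comorbidity)?
2. Which **genes** can be assigned to each phenotype through the genomic
   segments its patients share?
3. Which groups of comorbid phenotypes form **functionally coherent
   clusters**, i.e. share an underlying functional system (a pathway-like
   gene set)?

# The association statistic

Every association through a shared patient layer is scored with the
*hypergeometric index*. For two entities with marginal patient counts
$n_a$ and $n_b$ in a cohort of $N$ patients sharing $k$ patients,

$$ \mathrm{index} = -\log_{10} P(X \ge k), \qquad
   X \sim \mathrm{Hypergeom}(N, n_a, n_b). $$

The tail is **inclusive** ($\ge k$), so $k = 0$ gives an index of exactly 0,
and the index is monotone in $k$ at fixed margins. An index of 2 corresponds
to a tail probability of 0.01, the default cut: pairs at or above it are
*more-specific* (treated as comorbid; ties go upward because the rule is
"greater than or equal to"), the rest *less-specific*. The same index and
threshold are reused for phenotype–SOR associations.

Numerically the tail is summed in log space: binomial terms from
`lchoose()`, combined by pairwise log-add-exp **from the top of the tail**,
so tails of $10^{-300}$ keep full relative precision. The test suite checks
the implementation against direct `dhyper` summation on the exhaustive grid
$N \le 60$ and against exact integer enumeration for $N \le 30$ (binomial
coefficients are exactly representable in doubles there; no
arbitrary-precision arithmetic is available, so the "exact rational" oracle
is realised as exact-integer-in-double enumeration on that range).

# From CNVs to genes: small overlapping regions

All patient CNVs (deletions and duplications pooled; a patient's intervals
are first reduced so a patient counts once per base) are broken at every
breakpoint (`GenomicRanges::disjoin`). Each atomic segment covered by **two
or more distinct patients** is a SOR. Adjacent segments are *not* merged even
when their patient sets coincide — the gene mapping is unaffected because the
union of segments is identical, and atomicity keeps the decomposition a pure
function of the breakpoint set.

Phenotype–SOR associations are scored with the hypergeometric index over the
shared patients ($N$ = full cohort size) and kept at index $\ge 2$. A SOR
then contributes every gene model it intersects by at least one base on the
same chromosome (strand ignored); a phenotype's gene set is the union over
its retained SORs.

Internally all intervals are `GRanges` (1-based, closed), the native
Bioconductor convention; BED input and the cohort TSV's CNV field are
declared 0-based half-open and converted at the I/O boundary only. Keeping a
single in-memory convention — rather than carrying 0-based half-open
coordinates through GRanges-based code — is where off-by-one errors are
actually avoided.

# Enrichment and the consistent/emergent classification

Over-representation of a gene list against a functional-system collection is
the upper hypergeometric tail of the overlap, with Benjamini–Hochberg
adjustment **within one subject** (one phenotype, or one pair union) across
the sets tested for it; sets with zero overlap are not tested. The universe
defaults to all genes in the collection, mirroring the default behaviour of
the standard ORA tools; it is configurable. Significance means adjusted
$p < 0.05$.

For a pair $(a, b)$ with gene union $G_a \cup G_b$, each functional system F
is labelled:

* **consistent** — F significant for $a$, for $b$, and for the union;
* **emergent** — F significant for the union but for neither phenotype alone;
* no label otherwise (e.g. exactly one phenotype significant).

A system absent from a subject's tested records counts as not significant
there. The two labels are mutually exclusive by construction.

# Link communities and coherence

The network of pairs carrying at least one consistent or emergent label is
clustered by its **edges**: similarity of two edges sharing node $k$ is the
Jaccard index of the inclusive neighbourhoods of their non-shared endpoints,
non-adjacent edges have similarity 0, and edges are hierarchically clustered
on distance $1 - S$ with **average linkage** (single linkage is available
behind a flag, matching the method's original formulation). The dendrogram
is cut at the height maximising the partition density

$$ D = \frac{2}{M} \sum_c \frac{m_c\,\bigl(m_c - (n_c - 1)\bigr)}
        {(n_c - 2)(n_c - 1)}, $$

where $m_c$ and $n_c$ are a community's edge and node counts and a
two-node community contributes 0. Ties between cut heights are resolved
toward the **lower** height (finer clustering), deterministically. Average
linkage is monotone, so non-decreasing heights are enforced only against
floating-point noise (`cummax`). Single-edge communities are reported but
flagged trivial rather than silently dropped.

A cluster (the node set induced by an edge community) is **functionally
coherent** for F when at least a fraction $\theta$ (default 0.70) of its
phenotypes either are individually significant for F or are an endpoint of an
in-cluster pair labelled consistent/emergent for F. A disease overlaps a
cluster when its annotation misses at most one cluster phenotype (default;
configurable).

# Null models

Three randomisations calibrate every comparison:

* **links-based** — degree-preserving double-edge swaps (rejecting
  self-loops and parallel edges; target $10 \times |E|$ accepted swaps with a
  bounded attempt budget). Every node keeps its exact degree, so phenotype
  prevalence structure is retained; this is the primary comparison model.
* **nodes-based** — one uniform permutation of the phenotype labels; the
  degree multiset and $|E|$ are kept, individual degrees change.
* **SOR gene-content** — every SOR keeps its phenotype associations and its
  gene count but its genes are redrawn from the pool of genes appearing in
  any SOR; repeated 100 times, it yields the null distribution of
  phenotype–FunSys association counts.

Sampling of less-specific and unconnected pair lists to the more-specific
length uses 50 replicates; each replicate draws from a child seed derived
from (root seed, replicate id), so replicates are independently reproducible.

# Validation statistics

* **Pair–disease overlap** counts pairs whose two phenotypes co-occur in at
  least 1, 2, or 3 diseases.
* **Literature co-mention** is a one-sided (enrichment) Fisher exact test on
  the $2 \times 2$ abstract table; the universe is the number of distinct
  abstract ids in the corpus file (the natural choice for a pre-resolved
  corpus; configurable in principle by editing the corpus). One-sidedness is
  a deliberate choice: the question is over-representation of joint mention.
* **Phenotype–gene co-mention** counts map pairs sharing at least one
  abstract; the null permutes the gene-to-abstract-set assignment among the
  map's genes, preserving the multiset of abstract-set sizes.
* **Resnik similarity** between two terms is the information content of
  their most informative common ancestor, normalised by the maximum IC so
  scores live in $[0, 1]$; IC uses natural log of the annotation probability
  with counts propagated to ancestors over the disease-annotation corpus. A
  never-annotated term has undefined IC and is an error, not a silent zero.
* **Cluster semantic score**: mean within-cluster pairwise similarity pooled
  over clusters, against a null that redistributes the pooled phenotype
  multiset over clusters of identical sizes. Reported z-scores are always
  $(\mathrm{obs} - \mu_{\mathrm{null}})/\sigma_{\mathrm{null}}$; when
  $\sigma_{\mathrm{null}} = 0$ the z is reported as undefined.
* **Patient cluster support**: for each patient, the maximum number of their
  phenotypes co-located in one cluster, summarised at $\ge 2$ and $\ge 3$,
  against the same cluster-randomisation null.

# The synthetic scenario

Real cohorts of this kind are access-restricted, so the generator plants the
structure the method is designed to detect, at desk scale. Defaults (the
package's study conditions): 500 patients, 200 background phenotype terms,
5 modules of 3–5 phenotypes, background phenotype rate 0.02, five general
phenotypes at prevalence 0.3 (reproducing the high-prevalence/low-specificity
regime that the more/less-specific split must separate), noise CNVs on 20%
of non-carriers, breakpoint jitter ±3 kb, 50 decoy gene sets.

Each module has (i) 20 *comorbid carriers* sharing a 200 kb common locus and
the full module phenotype set at penetrance 0.9 — this drives pair
comorbidity — and (ii) 5 *private carriers* per phenotype whose CNV covers a
phenotype-specific 3-gene slice of the module's planted functional system.
The common locus carries 100 background genes in four housekeeping-style
sets. Consequently each phenotype's inferred gene set is (background genes +
its own slice): the planted system is **not** significant for any phenotype
alone (3 of its genes among ~103, about the chance expectation) but **is**
significant for a pair's union (6 genes, far above expectation), which is
exactly the emergent configuration; the housekeeping sets are consistent for
every pair and hold the cluster graph together even when a slice association
is lost to penetrance.

What the generator does *not* emulate: genome-scale gene density, inheritance
models, dosage direction effects, SNVs, term-frequency structure of real
literature, and the deep hierarchy of a real phenotype ontology (the
synthetic ontology is two levels). Passing recovery tests therefore shows the
pipeline detects the planted mechanism under realistic noise — not that real
cohorts will yield comparable effect sizes.

Recovery of a planted cluster is scored by **containment**: the planted
phenotype set must appear inside a coherent, non-trivial cluster. Exact-set
matching would penalise "hitchhiker" phenotypes that the generator's own
randomness makes genuinely comorbid with a module (a background phenotype
landing in several carriers co-occurs with the module and maps to its locus;
by the method's definitions it belongs in the cluster).

# Problem sizes in the test suite

The packaged tests run the hypergeometric oracle on the exhaustive
$N \le 60$ grid, the Fisher oracle on $U \le 40$, link-community optimality
on 200 random graphs of up to 7 edges against an exhaustive-cut oracle, the
null-model invariants on 100 seeded runs each, SOR correctness against a
per-base depth oracle on 50 random fixtures, and parameter recovery on 50
replicates of the default scenario. These sizes were chosen as the smallest
grids that exercise every code path and boundary; the acceptance script runs
the full workflow once at the default scenario.

# Known limitations

* The double-edge-swap sampler targets $10 \times |E|$ accepted swaps and
  warns when the attempt budget is reached first (nearly-complete graphs
  admit few legal swaps); degrees are asserted in every case.
* The dense edge-distance matrix limits link clustering to networks of a few
  thousand labelled edges; labelled comorbidity networks are far smaller in
  practice because labels require mapped genes and significant unions.
* Dosage direction (deletion vs duplication) is recorded but not used by the
  association logic.
* The ORA universe and minimum-set-size conventions of external tools vary;
  ours (collection universe, minimum overlap 1) are documented rather than
  asserted to be identical to any specific tool's defaults.
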