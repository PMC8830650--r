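---
title: "Discrete HMM inference, step by step: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete HMM inference, step by step}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmtutor)
```

## The model

A discrete first-order hidden Markov model describes an unobserved Markov
chain of *hidden states* $q_1, \dots, q_L$ that emits one observed symbol
$o_j$ per position. Six elements specify it completely:

1. the observed sequence $O = o_1 \dots o_L$ (the query);
2. the alphabet of observed symbols (DNA, RNA, the 20 amino acids, or any
   custom set);
3. the set of $K$ hidden states;
4. the prior vector $\pi(k) = P(q_1 = k)$ — needed because position 1 has
   no predecessor;
5. the transition matrix $a(k \to l) = P(q_{j+1} = l \mid q_j = k)$;
6. the emission matrix $e(k, b) = P(o_j = b \mid q_j = k)$.

`hmm_model()` assembles elements 2–6 in that order and validates them
jointly; `hmm_sequence()` binds element 1 to the alphabet. The package is
deliberately restricted to this basic architecture: no begin/end states, no
higher-order dependencies, no continuous emissions, no parameter training.
It is a calculator for *variables modeling* — choosing states, alphabets
and parameters and seeing their consequences — not a trainer.

## The three questions and their algorithms

Given a model and a sequence, three classical dynamic programs answer three
questions (all tables are $L \times K$, positions 1-based):

**Forward** — *what is the probability of the observed sequence under the
model?*
$$\alpha_{1,k} = \pi(k)\, e(k, o_1), \qquad
\alpha_{j,l} = e(l, o_j) \sum_k \alpha_{j-1,k}\, a(k \to l), \qquad
P(O) = \sum_k \alpha_{L,k}.$$

**Backward** — suffix probabilities, and with Forward the per-position
posteriors:
$$\beta_{L,k} = 1, \qquad
\beta_{j,k} = \sum_l a(k \to l)\, e(l, o_{j+1})\, \beta_{j+1,l}, \qquad
P(O) = \sum_k \pi(k)\, e(k, o_1)\, \beta_{1,k}.$$

**Viterbi** — *the most probable hidden path:*
$$\delta_{1,k} = \pi(k)\, e(k, o_1), \qquad
\delta_{j,l} = e(l, o_j)\, \max_k \delta_{j-1,k}\, a(k \to l),$$
with traceback from $\arg\max_k \delta_{L,k}$.

**Posterior decoding** combines the first two:
$\gamma_{j,k} = \alpha_{j,k}\beta_{j,k} / P(O)$, one probability curve per
state along the sequence. `posterior_chart_data()` and
`plot()` expose it as chart data.

```{r example}
fx <- load_fixture("tm_p18599")
fw <- hmm_forward(fx$model, fx$sequence)
fw$log_total / log(10)   # log10 P(O)
vit <- hmm_viterbi(fx$model, fx$sequence)
table(vit$path)
```

## Numerical choices

* **Log space is the default.** A 100-residue protein query already has
  $P(O) \approx 10^{-124}$; at $L \approx 1000$ plain double-precision
  products underflow entirely. All sums in log mode go through a
  max-shifted log-sum-exp, so no intermediate quantity underflows. Plain
  mode is retained because the step-by-step reports are far more readable
  with literal probabilities, which is the point of a teaching tool.
* **Zeros are first-class.** A zero probability is a modeling statement
  (the worked example *requires* impossible inside↔outside transitions);
  it maps to $-\infty$ in log space, and the log-sum-exp guard keeps
  all-$-\infty$ sums at $-\infty$ rather than NaN. A model × sequence pair
  with $P(O) = 0$ raises a clear diagnostic in Viterbi and posterior
  decoding.
* **Ties break toward the earliest declared state**, both in the Viterbi
  maximization and in the traceback. This makes output deterministic, and
  it is mirrored exactly in the enumeration oracle's sort order (descending
  probability, then state indices compared from the last position
  backwards — the order a traceback resolves ties in).
* **Normalization tolerance** is $|{\sum} - 1| \le 10^{-9}$ for the prior
  and every matrix row. There is no silent renormalization: surfacing
  data-entry errors is pedagogically useful. An explicit
  `renormalize = TRUE` exists for deliberately unnormalized input.
* **Reported Viterbi probability** is the conditional
  $P(Q^* \mid O) = \exp(\log P(Q^*, O) - \log P(O))$, alongside the joint;
  the conditional is the number a reader can compare across sequences.
* **Unknown symbols** are an error by default. Opting in
  (`allow_unknown = TRUE`) treats an unknown symbol as emitted with
  probability $1/|\text{alphabet}|$ from every state — a deliberately
  uninformative column that leaves the posterior driven by the
  neighbours. Ambiguity codes are not modelled.

## The enumeration oracle

Everything the dynamic programs compute is also computable by brute force:
`enumerate_paths()` lists all $K^L$ paths with their exact joint
probabilities $P(Q, O)$ via `joint_probability()`, and
`posterior_by_enumeration()` derives $\gamma$ from the definition. The test
suite holds the two routes to each other within a relative $10^{-9}$ on
hundreds of randomly generated small instances ($K \le 3$,
$|\text{alphabet}| \le 4$, $L \le 6$ — sizes where $K^L \le 729$ keeps the
enumeration exact, fast and far from underflow). The oracle works in plain
probability space only and refuses instances above a path cap (default
$10^6$); it is deliberately unoptimized, because its value is being
obviously correct.

## Random models

`random_hmm()` fills the prior and every matrix row with normalized
independent uniform(0,1) variates — the flat Dirichlet distribution, the
natural "no preference" choice over probability vectors. The seed is
mandatory and consumed by R's Mersenne-Twister in an isolated RNG scope
(`withr::with_seed`), so the same `(n_states, alphabet, seed)` is
bit-for-bit reproducible and the caller's RNG stream is untouched.

## The worked example and its synthetic parameters

The bundled fixture `tm_p18599` is a transmembrane-topology exercise: the
first 100 residues of the 5-hydroxytryptamine receptor 2A (UniProtKB
P18599) bound to a 3-state model — I (inside/cytosolic), M
(membrane-embedded), O (outside). Real topology predictors use far richer
state architectures; three states is the minimal model that still teaches
the idea.

The fixture's parameters are **synthetic surrogates, not trained values**
(the file is named accordingly). They were fixed once, from first
principles, before any inference was run:

* prior $(I, M, O) = (0.6, 0.1, 0.3)$ — a translated N-terminus is most
  often cytosolic;
* transitions with $a(I \to O) = a(O \to I) = 0$ (a chain cannot jump
  across the membrane without traversing it) and self-transitions near 1
  for I and M ($0.98$ and $0.95$), giving geometrically distributed
  segment lengths of realistic scale (mean $\sim 50$ and $\sim 20$
  residues);
* emissions built from background amino-acid frequencies: the M row
  reweighted by $\exp(0.7 \cdot \text{Kyte–Doolittle hydropathy})$
  (membrane helices are strongly hydrophobic), the I row with lysine and
  arginine enriched $\times 1.8$ (the positive-inside rule), the O row
  with polar residues $\times 1.4$.

What passing tests on this fixture show is therefore *structural*:
round-trip integrity of the sequence, validity of the model, and the hard
consequence of the zero transitions — no decoded path can ever place I and
O adjacently. What they cannot show is agreement with any published
prediction for this protein: surrogate parameters yield their own decoding
(with these values, a terminal membrane run and a hydrophilic head
assigned to the O state), and no such agreement is asserted anywhere.
Synthetic data more generally: the property tests sample models from the
flat Dirichlet, which covers parameter space evenly but does not emulate
the sparse, spiked matrices of trained biological models except through
the explicit zero-structure cases in the suite.

## Reports

`render_report()` reproduces the classroom experience: a parameter echo,
then one section per algorithm with its recursion, cell-by-cell expanded
arithmetic, the full value table, and the final result (P(O) in scientific
notation; $Q^*$ aligned under the observations in 60-column ruled blocks
with $P(Q^* \mid O)$; the posterior chart data). For $L \le 15$ every cell
is expanded; beyond that only the first 3 and last 2 positions are, which
keeps the 100-residue report readable while still showing the recursion's
mechanics at both boundaries. Displayed numbers are rounded copies (4
significant digits, scientific below $10^{-4}$); computations always use
the stored full-precision values. Text, Markdown and self-contained HTML
outputs carry the same content.

## Problem sizes used in the checks

The automated checks run 200 oracle-vs-DP instances at $K \le 3$,
$|\text{alphabet}| \le 4$, $L \le 6$, a 16-sequence conservation sweep
($K = 2$, $|\text{alphabet}| = 2$, $L = 4$, verifying
$\sum_O P(O) = 1$), and the full 100-residue example in log space — sizes
chosen so the whole suite gives exact-enumeration coverage in seconds.

## Known limitations

No Baum–Welch or Viterbi training, no model validation machinery
(cross-validation, ROC), no begin/end states, no N-best paths, no
sliding-window smoothing of posteriors (a feature of production topology
predictors, deliberately out of scope), and plain mode underflows for long
sequences by design. The FASTA reader handles standard multi-record files
only; fetching sequences from remote databases is out of scope.
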