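# hmmtutor

A teaching-oriented R toolkit for discrete first-order Hidden Markov
Models (HMMs). It is written for people learning — or teaching — how the
basic HMM machinery actually works: you specify the six elements of a
model by hand (alphabet, hidden states, prior vector π, transition matrix
a, emission matrix e, and the observed query sequence O), interrogate it
with the three classical algorithms, and get a step-by-step report of
every recursion cell, not just the final numbers.

The three questions and their algorithms:

* **Forward** — what is the probability P(O) of the observed sequence
  under the model?
  α₁ₖ = π(k)·e(k,o₁); αⱼₗ = e(l,oⱼ)·Σₖ αⱼ₋₁,ₖ·a(k→l); P(O) = Σₖ α_{L,k}.
* **Viterbi** — what is the most probable hidden-state path Q*?
  δ₁ₖ = π(k)·e(k,o₁); δⱼₗ = e(l,oⱼ)·maxₖ δⱼ₋₁,ₖ·a(k→l), with traceback.
* **Backward / posterior decoding** — what is the probability that state
  k emitted the symbol at position j?
  β_{L,k} = 1; βⱼₖ = Σₗ a(k→l)·e(l,oⱼ₊₁)·βⱼ₊₁,ₗ;
  γⱼₖ = αⱼₖ·βⱼₖ / P(O), plotted as one curve per state along the sequence.

Everything runs in log space by default (log-sum-exp sums), with a plain
probability mode for readable classroom reports. A brute-force oracle
(`enumerate_paths()`) recomputes every quantity by exhaustive path
enumeration and backs the test suite. Models can be written/read as
structured text files, generated randomly from a seed (`random_hmm()`),
and driven from the shell via the bundled `hmm` script.

## A worked toy example

A two-state model of a protein-like string: state `M` (membrane-like,
prefers the hydrophobic symbol `H`) and state `W` (water-exposed, prefers
`L`).

```r
library(hmmtutor)
ab <- hmm_alphabet("custom", c("H", "L"))
m  <- hmm_model(ab, c("M", "W"),
                prior       = c(0.5, 0.5),
                transitions = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                emissions   = rbind(c(0.8, 0.2), c(0.3, 0.7)))
s  <- hmm_sequence("HHLLL", ab)

hmm_forward(m, s, mode = "plain")
#> <hmm_forward> L = 5, K = 2, mode = plain
#> P(O) = 0.0219101  (log = -3.820808)

hmm_viterbi(m, s, mode = "plain")
#> <hmm_viterbi> L = 5, mode = plain
#> Q* = MMWWW
#> P(Q*, O) = 0.00632218,  P(Q* | O) = 0.288551

round(hmm_posterior(m, s)$table, 4)
#>           M      W
#> [1,] 0.6322 0.3678
#> [2,] 0.5679 0.4321
#> [3,] 0.2306 0.7694
#> [4,] 0.1415 0.8585
#> [5,] 0.1591 0.8409
```

Reading the output: the five-symbol query has total probability ≈ 0.0219
summed over all 2⁵ = 32 hidden paths; the single best path `MMWWW`
carries ≈ 29% of that mass; and the posterior matrix shows, per position,
how confident the model is in each state — here the switch from `M` to
`W` happens at position 3, where the symbols turn hydrophilic.
`render_report(m, s, list(...))` turns the same results into a full
step-by-step derivation (text, Markdown or HTML).

## The bundled transmembrane example

`load_fixture("tm_p18599")` ships the classic classroom exercise: the
first 100 residues of the 5-hydroxytryptamine receptor 2A (UniProtKB
P18599) with a 3-state topology model — I (inside), M (membrane), O
(outside). Its parameters are clearly-labelled **synthetic surrogates**
built from amino-acid background frequencies and hydropathy (see the
vignette), satisfying the structural constraints of membrane topology:
I↔O transitions are impossible (probability 0) and I/M self-transitions
are near 1.

```r
fx <- load_fixture("tm_p18599")
fw <- hmm_forward(fx$model, fx$sequence)
fw$log_total / log(10)
#> [1] -124.1817                 # P(O) ~ 10^-124: why log space matters
vit <- hmm_viterbi(fx$model, fx$sequence)
rle(vit$path)
#> Run Length Encoding: O x 82, M x 18   (no I-O adjacency, by construction)
```

## Command line

```sh
HMM=$(Rscript -e 'cat(system.file("cli", "hmm", package = "hmmtutor"))')
$HMM random --states 3 --alphabet DNA --seed 7 --out model.txt
$HMM validate --model model.txt
$HMM run --model model.txt --seq ACGTACGT --algorithms forward,viterbi
$HMM fixture --name tm_p18599 --out report.txt --posterior-tsv gamma.tsv
```

Exit status is 0 on success and nonzero with a one-line diagnostic
otherwise.

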