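---
title: "Searching di-PWM motifs: model, algorithms and design notes"
author: "dipwmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching di-PWM motifs: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipwmscan)
library(dplyr)
```

## The motif model

Transcription-factor binding sites are commonly summarized as probabilistic
motifs. The classical position weight matrix (PWM) scores each nucleotide at
each motif position independently, ignoring any dependency between adjacent
positions even though neighboring bases jointly shape DNA geometry and
protein contacts. The dinucleotide PWM (di-PWM) keeps the additive matrix
form but scores *pairs* of adjacent positions: a motif of length $m$ has
$m-1$ columns, and column $i$ assigns a weight $P[\alpha\beta, i]$ to each
of the 16 dinucleotides $\alpha\beta$. The score of a word
$w = w_1 \dots w_m$ is

$$\mathrm{score}(w) \;=\; \sum_{i=1}^{m-1} P[w_i w_{i+1},\, i],$$

so consecutive columns overlap by one letter. Databases such as HOCOMOCO
distribute di-PWMs of human and mouse transcription factors in exactly this
shape; `read_dipwm()` reads that flat layout (rows = columns of the motif,
16 lexicographically ordered dinucleotide weights per row). Weights are
treated as arbitrary finite reals — typically log-odds-like, but nothing in
the algorithms assumes a distributional origin.

## Thresholds

An occurrence is a length-$m$ window whose score reaches a threshold $t$.
Three threshold modes are supported:

* **absolute score** — used as is;
* **score ratio** $r \in [0,1]$ — resolved as
  $\theta = (\mathrm{score}_{\max}-\mathrm{score}_{\min})\, r +
  \mathrm{score}_{\min}$, the relative-score convention that makes
  thresholds comparable across matrices;
* **P-value** $p$ — resolved through the exact score distribution under a
  background model (below) as the smallest score whose tail probability is
  at most $p$.

The extrema $\mathrm{score}_{\min}, \mathrm{score}_{\max}$ come from the
lookahead recurrence (max/min variants), never from enumerating $4^m$ words.

Comparison with the threshold is `>=` rather than `>`: with a strict
inequality a ratio-1 threshold would return the empty set instead of the
maximal-score word(s), and the non-strict rule is the one under which all
algorithm equivalences are stated cleanly. All score-vs-threshold
comparisons share an absolute tolerance of $10^{-9}$: window scores
accumulate left to right while the extrema come from a right-to-left
recurrence, so exact float equality at a ratio-1 threshold would otherwise
depend on summation order.

## LookAhead and LookBack matrices

The LookAheadMatrix (LAM) is a $4 \times m$ table:
$\mathrm{LAM}[\alpha, i]$ is the best achievable score over columns
$i..m-1$ of any suffix whose letter at position $i$ is $\alpha$, with
boundary column $m$ identically zero (the table is stored with the extra
trivial column so the recurrence

$$\mathrm{LAM}[\alpha,i] = \max_\beta \big( P[\alpha\beta,i] +
\mathrm{LAM}[\beta,i+1] \big)$$

and the core bound below are uniform). Construction costs
$O(\sigma^2 (m-1))$ with $\sigma = 4$. The crucial property is
*realizability*: every entry is attained by a concrete word, recoverable by
greedy argmax traceback. The LookBackMatrix (LBM) is the mirror image for
prefixes ending with a given letter.

## Enumeration strategy

Scanning every window and computing its score takes $O(m\,|T|)$ time. The
enumeration strategy instead first enumerates every *valid word* — each
length-$m$ word with score $\ge t$ — and then locates all of them in the
text with a multi-pattern matcher in a single pass, so the scanning phase
computes no scores at all.

**Full enumeration (FE).** A depth-first walk of the trie of ACGT words.
After extending a prefix to length $\ell$ with last letter $\gamma$, the
branch survives only if
$\mathrm{partial} + \mathrm{LAM}[\gamma, \ell] \ge t$. By realizability,
every surviving branch leads to at least one valid word, so the work
between two emitted words is bounded by about $2m$ trie nodes and the
enumeration is linear in its output size (the test suite asserts the node
bound with an instrumented counter rather than wall-clock time). Words are
emitted in lexicographic order for reproducible output files.

**Selectivity and the core (CE).** Some database di-PWMs contain runs of
nonselective columns whose 16 weights are almost equal; restricted to such
a run, nearly every word is valid and the full word set explodes. Column
selectivity is measured as the population standard deviation of the 16
column weights. The *core* is the column interval of length at least 10
maximizing the average column standard deviation, found by exhaustive scan
over all $O(m^2)$ intervals; ties prefer the shorter, then the leftmost
interval, for determinism. "Length at least 10" counts matrix columns
(core words of $\ge 11$ nucleotides), since the dispersions being averaged
are per-column quantities; when the motif has at most 10 columns the whole
matrix is the core.

Core enumeration spells words $w$ of length $h = b-a+2$ over core columns
$a..b$. A core word cannot be selected on its own partial score, so the
bound is the best score of any full-length word containing it:

$$\mathrm{best}(w) = \mathrm{LBM}[w_1, a] +
\sum_{j=a}^{b} P[w_{j-a+1} w_{j-a+2},\, j] + \mathrm{LAM}[w_h, b+1].$$

The prefix term covers columns $1..a-1$ conditioned on the letter at
position $a$ being $w_1$, and the suffix term covers columns $b+1..m-1$
conditioned on the letter at position $b+1$ being $w_h$ — the only reading
under which the overlapping dinucleotide columns chain consistently and
the assembled word has length exactly $m$. Realizability of both tables
makes the core word set *exactly* the set of core substrings of valid
words: no false negatives, and nothing unreachable.

After locating core words, each hit at sequence position $p$ proposes the
full window starting at $s = p - k$ (with $k = a-1$ the core offset);
windows truncated by sequence ends are discarded, duplicates reached via
several core hits are scored once, and the window is rescored against the
full matrix before being reported.

**Window scanner (OS).** A scanning fallback that accumulates column
scores left to right and abandons a window as soon as
$\mathrm{partial} + \mathrm{LAM}[\gamma,\ell] < t$. It emits exactly what a
full scan would and needs no enumeration, which makes it the right choice
when the word set would exceed the cap (default 5,000,000 words) that
protects CE/FE from nonselective matrices at permissive thresholds.

All three algorithms return identical occurrence sets; the test suite
checks this four ways (CE = FE = OS = an independent naive scanner) on
randomized instances, on both strands.

## Matching, IUPAC codes, strands

Exact location of the word set in the text uses the Biostrings
constant-width dictionary matcher (`PDict`/`matchPDict`), which reports
every occurrence of every pattern in one pass with construction linear in
the cumulated word length — the same contract as an Aho–Corasick automaton.

Sequences may contain the 15 IUPAC ambiguity codes. The semantics is
*exists-disambiguation*: a window matches a word when choosing one letter
from each code's set can produce that word, and the reported score of an
ambiguous window is the maximum of the word scores over all compatible
disambiguations, computed by a best-path dynamic program over
(position, allowed letter) states in $O(m \sigma^2)$ per window — never by
expanding the product of disambiguations. This is the only semantics under
which plain-ACGT behavior is a strict special case and scores stay well
defined; occurrences on ambiguous windows carry `ambiguous = TRUE` so users
can filter them. Within the matcher, ambiguity-free windows come from the
exact dictionary pass (a code in the subject never matches a letter
pattern), and the few windows overlapping a code are checked by per-position
set membership against the word set.

The reverse strand (searched by default) is handled by scanning the
IUPAC-aware reverse complement of each sequence and mapping coordinates
back to the forward strand; a reverse-strand occurrence's score equals the
forward score of the reverse-complemented window word. Overlapping
occurrences are all reported; there is no greedy masking.

## P-values

The tool can resolve a P-value threshold and annotate occurrences with
P-values: the probability that a random background word scores at least as
high. The background model is order-0 i.i.d. letters, uniform by default —
the least-assumption null that is standard in PWM practice — with
user-settable frequencies; an order-1 Markov background is a documented
non-goal of this version. Column scores are discretized to bins of width
$\varepsilon$ (default $10^{-3}$ score units, exposed as a parameter) and
the mass is propagated over (last letter, binned partial score) states in
$O(m \sigma^2 B)$ for $B$ bins. Each word's score moves by at most
$(m-1)\varepsilon/2$ under binning; query scores are binned by `floor` so a
reported P-value never understates the true tail. Unattainable outer bins
(per-column maxima need not chain into any word) are trimmed so the support
bounds are attained. `threshold_from_pvalue()` returns the smallest binned
score whose tail is at most $p$, which inverts the survival function to
within one bin.

## The synthetic data generator

Because everything here is deterministic given a matrix and a sequence,
the package ships a generator that creates complete, self-validating test
instances without any downloads:

* matrices: each column's weights are $\log_2$ ratios of Dirichlet-sampled
  dinucleotide frequencies against the uniform $1/16$ (concentration 0.5
  by default — peaked, selective columns; larger values emulate the flat,
  nonselective columns that motivate the core);
* sequences: i.i.d. uniform ACGT letters with words drawn from the top
  scorers (ratio threshold 0.97, near-maximal) planted at recorded
  non-overlapping positions — the truth table every search must recover;
* optional ambiguity injection: letters inside planted words are replaced
  at a given rate by a random IUPAC code whose set contains the original
  letter, so the plant stays recoverable under exists-disambiguation
  matching.

What this emulates — and what it does not: uniform background sequence has
no repeat structure, GC skew or compositional patchiness, and planted
occurrences are sampled independently rather than clustered as real
binding sites are. Passing tests therefore demonstrate algorithmic
correctness (set equalities against brute force, planted-truth recovery,
P-value calibration against exhaustive counting), not biological
sensitivity or specificity on genomic sequence.

## Numerical and design choices

* Scores are doubles; all equality checks in tests use absolute tolerance
  $10^{-9}$, matching the threshold-comparison tolerance above.
* Coordinates are 1-based inclusive internally and in TSV output; BED6
  output is 0-based half-open with the motif score rescaled to
  $[0, 1000]$. Both are offered because downstream consumers are split on
  the convention.
* Ties in core selection (equal average dispersion) resolve to the
  shorter, then leftmost interval; enumeration order is lexicographic;
  occurrence output is sorted by (sequence, start, strand) — all fixed so
  identical inputs yield byte-identical outputs.
* Degenerate inputs: an empty word set yields a matcher that never fires;
  a threshold above the maximal score yields empty results rather than an
  error; sequences shorter than the motif yield no windows; a zero-width
  score range maps all BED scores to 0.
* The problem sizes exercised by the test suite (matrices up to $m = 14$,
  sequences up to 50 kb, exhaustive oracles up to $4^{10}$ words) were
  chosen so every brute-force oracle remains exact while the full suite
  runs in about a minute.

## Known limitations

* Only ACGT motifs over DNA; no mononucleotide-PWM mode, no motif
  construction from alignments or ChIP-seq counts.
* The P-value null is order-0; genomic backgrounds with strong
  dinucleotide composition are better served by supplying empirical letter
  frequencies, and even then the null ignores order-1 structure.
* Long runs of ambiguity codes make every window ambiguous and push the
  matcher into per-window checks; the contract holds but the linear-scan
  advantage fades.
* Valid-word sets are rebuilt per search; persisting them to word-list
  files (`write_words()`/`read_words()`) is supported, but no on-disk
  index of the searched sequence is provided.
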