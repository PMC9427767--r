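---
title: "Minimum-description-length induction of morpho-phonological grammars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-description-length induction of morpho-phonological grammars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonosynth)
```

## The model

phonosynth induces a morpho-phonological grammar from a paradigm matrix: a
table whose rows are stems (lexemes), whose columns are inflections, and
whose cells are observed surface forms written in IPA. A grammar has two
parts:

* a **lexicon** L mapping each stem to an underlying phoneme string and each
  inflection bundle to a prefix and a suffix (missing entries default to the
  empty string), and
* a **theory** T: an ordered sequence of SPE-style context-dependent rewrite
  rules `focus -> change / left _ right`.

A meaning `[stem: σ; i]` is realized by concatenating prefix, stem and
suffix and then applying the rules in order, one simultaneous pass each:

    surface = r1( r2 applied after r1, ... ( pfx(i) · stem(σ) · sfx(i) ))

The learner scores a candidate grammar by its total description length in
bits and demands that it reproduce **every** observed cell exactly; among
consistent grammars, the one with the smallest total length (rules + affixes
+ stems) wins. This hard-constraint MDL objective forbids wholesale
memorization: every word must be explained as rules operating on
concatenations of reusable morphemes, so a compact grammar must discover the
productive affixes and the sound processes that disturb them. Because every
distinct inflection bundle carries its own affix entries, fusional bundles
emulate arbitrary concatenative morphology (the lexicon can cache
concatenations of morphemes); inflectional classes are carried inside the
observed bundles rather than inferred.

Phonemes are vectors of signed binary features, so rules generalize across
sounds via natural classes (`[-sonorant]`, `C`, `V`, ...). Two feature
tables ship with the package — a full articulatory table and a reduced
"simple" acoustic table whose features are a strict subset — plus an atomic
mode in which phonemes are unanalysable symbols. These support ablation
experiments on the representation: the same search run with poorer features
or without feature matrices at all.

## Rules and their application semantics

A rule rewrites every site of the input where its focus matches and its
triggering environments occur immediately to the left and right. The
package commits to the standard conventions where the source formalism
leaves them open:

* matching is done against the **pre-rule** string and all matched sites are
  rewritten simultaneously, so a rule never feeds itself within one
  invocation (rules are non-cyclic, keeping the system finite-state);
* insertion sites (gaps) are enumerated left to right;
* a feature overwrite that lands on no (or no unique) inventory phoneme is
  an inventory gap and leaves that site unchanged;
* triggers hold at most two feature matrices, each optionally Kleene-starred
  (zero or more repetitions), with the word boundary `#` only at the outer
  end. This bounded shape covers the rule inventory the package is designed
  to search while keeping the space finite;
* one optional alpha variable links a trigger matrix to the overwrite, so a
  vowel-harmony process that copies the trigger's backness (say) is a single
  rule.

Rule order matters and is part of the theory: the first-listed rule applies
first. The classic English plural is the worked example: with suffix /z/,
ә-epenthesis between word-final stridents must precede progressive
devoicing, or /hɔrsz/ surfaces as */hɔrsәs/ instead of /hɔrsәz/.

## The description-length prior

All constants live in one YAML file (`inst/extdata/cost_model_default.yaml`)
and are echoed into result files. The defaults: 4 bits per rule, 1 per
feature literal, 2 per Kleene star, 2 per trigger element, 1 per boundary
symbol, 2 per alpha variable, 3 per lexicon or inserted phoneme.

Two of these deserve comment. A trigger is encoded as a sequence: each
element pays a continue-tag plus its literal contents, while the boundary is
a bare terminator variant, so an element costs more than `#` even when its
matrix is empty. Without this, the universal class `[ ]` would make "some
segment follows" free, and the complement of every word-edge context would
be as cheap as the context itself — in particular, an allophony problem
could never prefer "devoice word-finally" over "voice everywhere
non-finally", although only the former is the linguistically coherent
statement. Pricing the slot resolves the tie in the principled direction
for every edge-conditioned process at once.

Second, lexicon material can be coded two ways: a flat per-phoneme constant
(the default for grammar induction), or `log2(alphabet) + 1` bits per unit
plus a terminating stop bit ("uniform" coding). The uniform code is a true
subprobability over all finite strings, which the probabilistic scoring
layer needs: with it, the stem-likelihood bound really is a lower bound on a
marginal probability, and held-out word scores sum to at most one.

Consistency failure is reported as the distinguished value `INCONSISTENT`,
not as a large negative score; the objective is simply undefined for
grammars that do not reproduce the data.

## Synthesis backends

**Exact bounded search.** The exact backend enumerates every ordered rule
sequence up to `max_rules` (at most two) from a declared rule space, every
affix assignment from per-column candidate sets, and every stem up to
`max_stem_len`, and certifies the optimum within those bounds. The
enumeration is feasible because candidate theories are evaluated backwards:
for each observed cell the kernel computes the cell's preimage set under the
theory (inverting insertions by deleting copies of the inserted string,
deletions by re-inserting focus-class segments, overwrites via precomputed
source maps, every candidate verified by a forward pass), then factors each
preimage as prefix + stem + suffix. An inconsistent theory — the typical
case — usually dies on the first cell after a handful of preimage
expansions, instead of paying an exhaustive forward stem search. For
two-rule theories the inversion of the second rule is shared across all
first rules. The generation caps (at most 12 candidate overwrite positions
and 6 rewritten sites per application, at most 2 re-inserted deletions, a
2048-candidate cap per expansion) are part of the declared bounds; if a cap
is ever hit the result carries a truncation flag and the optimality claim
is weakened with a warning rather than silently.

Affix hypotheses come either from the full inventory up to `max_affix_len`
(the fully exact space, default) or from edge substrings of the observed
column forms (a documented data-driven restriction for larger problems).

**Incremental counterexample-driven search.** The incremental backend
starts from the empty theory and no data, repeatedly adds the earliest
failing lexeme's whole paradigm row (minibatch of one lexeme, configurable),
and repairs the theory with the smallest edit budget that restores
consistency, maximizing the objective within that budget. The edit metric
counts one unit per changed rule slot (focus, change, left, right) and four
per inserted or deleted rule, over an order-preserving alignment. Repair
explores budget levels 0, 1, 2 (slot edits), then 4 and up (rule insertion,
deletion, whole-rule replacement), and escalates to a global re-solve —
loudly — only if no budget suffices.

The incremental backend is deliberately greedy: once an early lexeme has
been explained by one process, later repairs at minimal edit distance keep
that commitment. On most small problems it lands exactly on the global
optimum; occasionally the optimum is a re-analysis (for instance an
insertion process with swapped affixes instead of final devoicing) that no
minimal repair can reach, and the incremental grammar pays a bit or two of
description length. This is the same trade-off the counterexample-driven
strategy makes at scale — locality is what keeps each solver call small —
and the package reports it honestly rather than papering over it with a
hidden global pass.

## Allophony problems

An allophony problem adds a substitution: a partial injective map pairing
each underlying phoneme with its contextual variant (chain shifts, where
domain and range overlap, are rejected). Both candidate lexica are built —
stems with the substitution applied, and stems with its inverse applied —
and a rule theory is synthesized for each; the direction with the higher
joint score wins, ties going to the first direction with a warning. A
problem counts as solved only when a rule actually explaining an
alternation is found (an empty substitution is trivially solved). On a
final-devoicing toy the voiced-underlying direction wins precisely because
of the trigger-slot coding above: `_ #` is cheaper than `_ [ ]`.

## Few-shot artificial-grammar learning

AGL stimuli are three-syllable CV words built from templates ABB, ABA, AAB,
AAx, AxA (A, B variable syllables, x a constant). The learner entertains a
small copy-grammar space: constant affixes (edge substrings of the training
words, up to two units) plus reduplicative rules, at most two. In
**syllabic** mode a rule copies a peripheral syllable to a word edge; in
**segmental** mode — the representation ablation — rules copy one phoneme
at a time (the segment at offset j from an edge), so reduplicating a CV
syllable takes two rule applications. This is the crucial asymmetry: with
one training word, the syllabic learner's copy analysis is about as cheap
as memorization and discrimination is immediate, while the segmental
learner must buy two rules before its stems shrink, so its posterior stays
near-uniform until several words amortize the cost. Both learners converge
with enough data.

Instead of committing to one grammar, the learner computes the full Pareto
frontier of the parsimony/fit trade-off (rule + affix bits against total
stem bits); the memorizing grammar always anchors one end. Held-out words
are scored by marginalizing over the frontier, each grammar weighted by its
normalized joint training probability and contributing its best-stem
likelihood bound for the new word. Discrimination is summarized as the mean
log-odds of matched consistent/inconsistent test pairs.

Because copy rules only add peripheral material and affixes are constant,
an underlying form is always a contiguous substring of its surface word;
the stem search exploits this, and the stop-bit coding keeps the implied
distribution over held-out words a subprobability.

## Metatheory learning

Across many problems the package can induce a fragment-grammar metatheory:
a PCFG over rule syntax trees (nonterminals for the rule, focus, change,
triggers, feature matrices, literals and phonemes; uniform initial
probabilities) augmented with cached fragments — partial trees with typed
holes, proposed by antiunifying pairs of rules drawn from each problem's
particle set of top-k grammars (k defaults to a desk-scale 10; the particle
refreshes use the same bounded synthesis with per-rule costs taken from the
metatheory instead of the flat constants). Fragments never extend the
generable language; they only reweight it. Parameters are refit by
Inside-Outside EM under a symmetric Dirichlet prior with pseudocounts 1, so
the penalized objective is monotone. A fragment is priced by generating it
from the grammar so far, with a Bernoulli stop probability of 0.5 at each
node deciding between recursing and leaving a hole; a proposal is accepted
only if the variational lower bound (metatheory prior plus per-problem
particle marginals) does not decrease — hillclimbing, not posterior
sampling. On a family of problems sharing a word-final devoicing process
the learned schema makes the shared rule substantially more probable and
steers re-solving toward it.

## The synthetic-problem generator

Recovery experiments need problems whose generating grammar is actually
recoverable, so the generator encodes what a curated textbook problem looks
like rather than sampling arbitrary strings:

* stems follow CV phonotactic templates (CV, CVC, VCV, CVCV, CVVC) and must
  jointly cover several distinct final segments, so edge-conditioned
  analyses are distinguishable from their complements;
* the base inflection is unaffixed and the other suffixes are nonempty and
  pairwise distinct;
* sampled rules are drawn from the bounded space in proportion to their
  prior, but only *conditioned* rules targeting a *proper* class are
  generated: an environment-free rewrite is silently absorbed into the
  stored stems, and a universal focus rewrites whole words beyond
  recognition — neither leaves a recoverable signal, and neither resembles
  a textbook process;
* every sampled rule must *alternate*: fire in at least one cell and stay
  silent in another cell of the same lexeme, so its effect cannot be
  compiled into a stem or an affix.

Even so, recovery is judged by observational equivalence on held-out stems,
not by syntactic identity: extensionally equivalent re-analyses (deletion
versus epenthesis, and the occasional genuinely ambiguous instance) are a
documented property of the problem class, which is why the recovery
criterion is a rate over seeds rather than a per-seed guarantee.

## Problem sizes and what the tests show

The test suite and the acceptance script run everything at desk scale, as
the package's own choice of study conditions: inventories of three to
twelve phonemes, two or three features, paradigms of two to five lexemes
with two or three inflections, rule bounds of one or two, twenty seeded
problems per experiment, fifteen test pairs per AGL condition, six datasets
for metatheory learning. At this scale the exact backend's optimality is
verified against an independent brute-force enumerator (a star-unrolling
matcher plus nested-loop search that shares no code with the kernel), and
the Pareto frontiers against full enumeration of the copy-grammar space.
Passing these tests shows that the machinery is correct on problems small
enough to certify; it does not show that the heuristics scale to
hundred-word corpora, that the bundled feature tables suit every language,
or that generated CV stimuli capture the distributional quirks of natural
elicitation data.

## Known limitations

Rule conjunction braces, mirror-image rules, metathesis and cyclic
application are outside the rule language; nonconcatenative morphology
beyond the AGL copy device is not handled; inflectional classes are read
from the data, never inferred; the kernel searches at most two rules per
theory (the incremental loop composes larger theories, but each repair is
bounded); and the incremental backend can pay a small description-length
penalty relative to the exact optimum, as discussed above.
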