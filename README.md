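# phonosynth

Grammar induction for morpho-phonology: given a small paradigm matrix of
surface forms (rows = stems, columns = inflections, cells = IPA strings),
phonosynth searches for the minimum-description-length grammar that exactly
reproduces every cell. A grammar is an ordered sequence of SPE-style
context-dependent rewrite rules

    focus -> change / left _ right        e.g.  [-sonorant] -> [-voice] / [-voice] _ #

together with a concatenative lexicon L (underlying stems, and a prefix and
suffix per inflection bundle). A meaning `[stem: σ; i]` surfaces as

    Phonology(Morphology([stem: σ; i])) = r1; r2; ...; rK  applied to  L(i, pfx) · L(σ, stem) · L(i, sfx)

and the learner maximizes the MAP objective: the prior probability
`2^-bits(T, L)` of the grammar under a description-length prior, subject to
the hard constraint that every observed ⟨form, meaning⟩ pair is derived
exactly. The package is aimed at computational linguists and cognitive
scientists who want a workbench for classic phonology problems: rule
discovery from textbook-style paradigms, allophony (which member of a
phoneme pair is underlying?), few-shot artificial-grammar-learning
simulations with Pareto-marginal Bayesian scoring, and fragment-grammar
"metatheory" induction across many problems.

Main entry points:

| function | what it does |
|---|---|
| `load_feature_system()`, `parse_rule()`, `apply_rule()` | feature matrices, SPE notation, one-pass rule application |
| `exact_synthesize()` / `incremental_synthesize()` | MDL-optimal grammar search (bounded-exact or counterexample-driven) |
| `pareto_synthesize()`, `agl_pareto()` | Pareto frontier of the parsimony/fit trade-off |
| `solve_allophony()` | underlying-form directionality for a phoneme substitution |
| `generate_stimuli()`, `score_heldout()`, `log_odds()` | AGL stimuli and few-shot discrimination |
| `learn_metatheory()`, `top_k_theories()`, `rule_prior()` | cross-problem fragment-grammar induction |
| `sample_problem()`, `read_problem()`, `write_grammar()` | synthetic problems and JSON I/O |

## Worked example: the English plural

Dogs, cats and horses pluralize as /dagz/, /kæts/ and /hɔrsәz/. The learner
sees only the six surface forms and must discover that the suffix is
underlyingly /z/, with two ordered sound processes repairing the
concatenations:

```r
library(phonosynth)

fs <- load_feature_system("articulatory",
  restrict = c("d","a","g","k","æ","t","h","ɔ","r","s","z","ә"))
X <- problem_data(tibble::tibble(
  stem_id    = rep(c("DOG","CAT","HORSE"), each = 2),
  inflection = rep(c("sg","pl"), 3),
  form       = c("dag","dagz","kæt","kæts","hɔrs","hɔrsәz")))
cfg <- synthesis_config(cost_model(), max_rules = 2,
  features = c("voice","strident"), allow_delete = FALSE,
  allow_star = FALSE, allow_prefixes = FALSE, max_affix_len = 1,
  affix_source = "inventory", max_stem_len = 4)
fit <- incremental_synthesize(X, cfg, fs)
fit
#> <synthesis_result> backend=incremental, objective=-53.00 bits
#> <theory>
#>   r1: ∅ -> ә / [+strident] _ [ ]
#>   r2: [ ] -> [-voice] / [-voice] _
#> stems:
#>   DOG: /dag/
#>   CAT: /kæt/
#>   HORSE: /hɔrs/
#>   sfx[infl:pl]: /z/
fit$trace
#> # A tibble: 3 × 6
#>       t lexemes cells budget escalated objective
#>   <int>   <int> <int>  <int> <lgl>         <dbl>
#> 1     1       1     2      0 FALSE           -12
#> 2     2       2     4      4 FALSE           -29
#> 3     3       3     6      4 FALSE           -53
```

The result reads: the best grammar costs 53 bits in total (20 for the two
rules, 3 for the suffix /z/, 30 for the ten stem phonemes). Rule r1 inserts
/ә/ between a strident and a following segment (that is what separates the
two sibilants in /hɔrs/+/z/ → /hɔrsәz/), and r2 devoices a segment after a
voiceless one (so /kæt/+/z/ → /kæts/, while /dag/+/z/ keeps its /z/ after
voiced /g/). The trace shows the counterexample-driven loop: DOG is
explained by the lexicon alone (edit budget 0), then CAT forces the
devoicing rule and HORSE the epenthesis rule (budget 4 = one rule insertion
each). Running `exact_synthesize()` instead certifies that 53 bits is
optimal in the declared search space. `tidy(fit)` and `glance(fit)` return
the grammar as tibbles; `autoplot()` on a `pareto_synthesize()`/
`agl_pareto()` result draws the parsimony/fit frontier.

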