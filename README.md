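# lexner — lexicon-enhanced Chinese NER with criss-cross attention

Named entity recognition in specialised Chinese text — agricultural
disease and pest writing is the motivating case — is hard for two
reasons: general-purpose word segmenters stumble over domain terms
(pesticide names, disease names, crop varieties), and plain
character-level taggers cannot use word information at all.  `lexner`
implements a complete pipeline that addresses both:

1. **Statistics-based new-word detection.**  Candidate strings of 2–4
   characters are harvested from raw text with sliding n-gram windows
   and filtered in turn by word frequency *WF*, mutual information

   *MI*(w₁, w₂) = log₂ p(w₁₂) / (p(w₁) p(w₂)),

   and left/right contextual (branching) entropy

   *Eₗ*(w) = −Σ p(wₗ|w) log₂ p(wₗ|w)   (and symmetrically *Eᵣ*).

   Default thresholds are *WF* ≥ 5, *MI* ≥ 3.9 bits, *CE* ≥ 2.7 bits.
   Detected words extend a dictionary segmenter (built-in forward
   maximum matching, with an adapter hook for external segmenters),
   which then segments an annotation corpus into the NER **lexicon**
   with word frequencies z(w).

2. **BMES word-set (Softlexicon) features.**  Each character cᵢ collects
   the lexicon words that contain it into four sets by position —
   B(cᵢ) (word begins at i), M(cᵢ) (interior), E(cᵢ) (ends at i),
   S(cᵢ) (single character) — and each set is condensed to a
   frequency-weighted embedding sum

   v(S) = (4/Z) Σ_{w∈S} z(w) eʷ(w),  Z = Σ_{B∪M∪E∪S} z(w).

   The attention-weighted extension feeds the stacked [d_w × 4] set map
   through a criss-cross attention block, maps the result to four logits
   through a learned affine map q, and gates each set with a sigmoid
   weight aᵢ ∈ (0, 1):

   x = [x_c; a₁v(B); a₂v(M); a₃v(E); a₄v(S)].

   Setting a ≡ 1 recovers the static Softlexicon feature exactly.

3. **BiLSTM–PCAT–CRF tagger.**  Fused features run through a BiLSTM;
   the encoder output, viewed as a C×W×1 feature map, passes a parallel
   criss-cross attention block (PCAT: a 1×1-conv branch and a 1×3-conv
   branch, each followed by criss-cross attention and a 1×3 conv, summed).
   Criss-cross attention attends over the H+W−1 row/column positions of
   each pixel and adds a residual; at H = 1 it is exactly dense softmax
   attention along the sentence.  A linear-chain CRF scores tag
   sequences; Viterbi decoding under a forbidden-transition mask
   guarantees well-formed BMES-O output.  Training minimises the CRF
   negative log-likelihood by mini-batch SGD (lr_e = lr₀/(1 + decay·e))
   through a small reverse-mode autodiff engine built into the package
   and verified against finite differences.

Evaluation is strict entity-level precision/recall/F1
(F₁ = 2PR/(P+R)), micro-averaged with per-category breakdowns.
A seeded synthetic-corpus generator (private-use-area pseudo-characters,
multi-character domain words, nested words, uneven category mix) makes
the whole pipeline testable without any external data.

## Worked example

```r
library(lexner)

lex <- lexicon(c("植物", "病害", "植物病害", "病"),
               c(2, 3, 1, 4))
ws <- match_word_sets("植物病害", lex, 2)   # character 物
print(ws)
#> B = { <NONE>:1 }
#> M = { 植物病害:1 }
#> E = { 植物:2 }
#> S = { <NONE>:1 }
word_sets_total(ws)
#> [1] 5
```

The interior character 物 is matched by exactly two lexicon words:
植物病害 strictly contains it (set M) and 植物 ends at it (set E); empty
sets hold the `<NONE>` placeholder with frequency 1, so the total mass
Z = 1+1+2+1 = 5 keeps the weighting defined.

Training the tagger on a 200-sentence synthetic corpus:

```r
spec  <- synth_spec(n_common_words = 40, n_domain_words = 24,
                    n_sentences = 200, mean_words = 4,
                    alphabet_size = 120, seed = 11)
corp  <- generate_corpora(generate_world(spec), spec)
fit   <- lexner(corp$tagged, corp$lexicon,
                model = model_config(d_char = 16, d_word = 16,
                                     lstm_hidden = 32, dropout = 0),
                train = train_config(batch_size = 8, lr = 0.3,
                                     epochs = 30, seed = 5, stop_f1 = 95))
print(fit)
#> Lexicon-enhanced BiLSTM-CRF tagger
#>   tagset:       25 tags ( 6 entity categories )
#>   vocab:        94 characters, 67 lexicon words
#>   dims:         d_char 16 | d_word 16 | LSTM hidden 32
#>   trained:      10 epochs, final loss 0.5563, entity F1 96.76
entity_prf(corp$tagged, predict(fit, corp$tagged))
#> Entity-level scores (micro): P 96.95  R 96.58  F1 96.76
#>   TP 254  FP 8  FN 9
```

The model memorises the corpus within ten epochs on one CPU; `predict`
returns well-formed BMES-O tag sequences, and `entity_prf` counts an
entity as correct only when its exact span and category match.

A command-line front end over the same functions lives in
`inst/cli/lexner.R` (subcommands `detect-newwords`, `build-lexicon`,
`synth`, `train`, `predict`, `eval`).

## Package layout

- `R/corpus_io.R` — tagged-corpus / lexicon / embedding I/O, span↔tag
  conversion
- `R/newword.R` — n-gram statistics, WF/MI/CE filtering, segmentation,
  lexicon construction
- `R/lexmatch.R` — trie-backed BMES word-set matching and weighting
- `R/autodiff.R` — reverse-mode autodiff engine
- `R/neural.R` — criss-cross attention, set gate, PCAT, linear-chain CRF
- `R/model.R` — the `lexner()` fitting function and S3 methods
- `R/evalmetrics.R` — strict entity-level P/R/F1
- `R/synthetic.R` — seeded synthetic corpus generator
- `vignettes/methods.Rmd` — modelling assumptions, parameter choices,
  limitations
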