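# ddilearn

Drug–drug interaction (DDI) prediction from multiple binary drug-feature
tables, with relation-regularized score learning, cold-start prediction,
and structure-based severity grading of predicted interactions.

## The problem and who this is for

When two drugs are co-administered, pharmacokinetic or pharmacodynamic
interactions can blunt efficacy or cause adverse reactions; screening
candidate combinations computationally is far cheaper than wet-lab
testing. `ddilearn` is aimed at cheminformatics and pharmacovigilance
researchers who have (a) a network of known interactions among *n* drugs
and (b) several binary descriptor tables per drug — pathways, enzymes,
targets, chemical substructures (e.g. the 881 PubChem substructure keys)
— and want to rank

- **unobserved pairs among the networked drugs** (goal 1), and
- **interactions of a new drug with no known interactions** (goal 2,
  cold start),

and to attach a MINOR / MODERATE / MAJOR severity grade to the predicted
pairs from molecular-structure similarity.

## The model

Let `J` be the `n × n` binary symmetric interaction matrix and
`H^i` (`n × n_i`, `i = 1..m`) the binary feature matrices. Each feature
space is mapped into the common interaction space by a non-negative
projection `Z^i`, and a score matrix `S` is learned jointly:

    min_{Z^i >= 0, S}  theta * sum_i ( ||S - H^i Z^i||_F^2 + ||J - H^i Z^i||_F^2 )
                     + lambda * sum_i ( tr((Z^i)' O Z^i) + tr((H^i)' O H^i) )
                     + ||S - J||_F^2 + sigma * tr( ((I - M) S)' M S )

where `O` is the all-ones matrix and `M` is a non-negative
self-representation of the network (each drug's row of `J` reconstructed
from the other drugs' rows, unit row sums, zero diagonal), learned first
by constrained multiplicative updates. The final term — relation
regularization — ties predicted scores to the relational structure of the
known network. Optimization alternates an exact linear solve for `S`
with multiplicative, non-negativity-preserving updates of the `Z^i`; the
objective decreases monotonically and in practice converges in a handful
of iterations. Goal-1 scores are the symmetrized `(S_ij + S_ji)/2`; a
cold-start drug with feature vectors `H*^i` is scored as
`J* = (sum_i H*^i Z^i) / (m + 1)`.

Severity grading uses a weighted fingerprint similarity

    sim(A, B) = alpha * Tanimoto + beta * Dice + (1 - alpha - beta) * cosine

(defaults `alpha = 0.5`, `beta = 0.2`, Open Babel FP2 fingerprints from
SMILES) to transfer recorded 1–100 severity scores from structurally
similar known interactors, then bands the score: 1–30 MINOR, 31–60
MODERATE, 61–100 MAJOR.

Evaluation follows two 5-fold cross-validation protocols (held-out pairs
for goal 1, held-out drugs for goal 2) with six metrics; AUPR is primary
because negatives vastly outnumber positives.

## Worked example

```r
library(ddilearn)

sim <- simulate_ddi_data(n = 60, m = 2, dims = c(40, 50), rank = 5,
                         density = 0.08, noise = 0, seed = 7)
model <- ddi_fit(sim$features, sim$network, goal = 1, seed = 1)
model
#> <ddi_model> 60 drugs, 2 feature space(s) [feature1, feature2]
#>   (lambda, theta, sigma) = (0.1, 1e-05, 0.001); converged at iteration 3
#>   final objective 2506.43

predict_within(model, data.frame(drug_a = c("SYN0001", "SYN0002"),
                                 drug_b = c("SYN0002", "SYN0017")))
#>    drug_a  drug_b        score known
#> 1 SYN0001 SYN0002 8.389381e-07 FALSE
#> 2 SYN0002 SYN0017 5.066095e-06 FALSE

ddi_crossval(sim$features, sim$network, goal = 2, k = 5, seed = 1)
#> <ddi_cv> goal 2, 5-fold (seed 1)
#>  fold recall precision      f1 accuracy     auc    aupr
#>  ...
#>  mean 0.8096    0.7968 0.78406  0.96493 0.98739 0.90404
#>    sd 0.1538    0.1416 0.07197  0.01266 0.01224 0.05575
```

The pair scores are small in magnitude (the feature term carries weight
`theta = 1e-5`) — only their ranking matters; `SYN0002–SYN0017` is the
stronger candidate here. The goal-2 report shows the cold-start
protocol recovering held-out drugs' interactions with mean AUC 0.987 on
this noise-free simulation.

Severity grading:

```r
fps <- smiles_fingerprint(c(drugC = "c1ccccc1CCN", drugA = "c1ccccc1CCNC"))
fingerprint_similarity(fps$drugC, fps$drugA)
#> [1] 0.8868134
infer_severity("drugC", data.frame(drug = "drugA", score = 40), fps)
#> <ddi_severity> score 40 -> MODERATE; 1 neighbour(s) used
```

A shell interface with subcommands `simulate`, `fit`, `predict`,
`evaluate`, `tune` and `severity` is installed at
`system.file("cli", "ddilearn.R", package = "ddilearn")`.

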