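# variant<TAB>canonical. Variants are 1-3 word lowercase sequences matched
# longest-first; canonical forms are singular and hyphenated.
chi square	chi-square
chisquare	chi-square
chi-squares	chi-square
chi squares	chi-square
chisquares	chi-square
chi-squared	chi-square
chi squared	chi-square
chisquared	chi-square
t test	t-test
ttest	t-test
t-tests	t-test
t tests	t-test
ttests	t-test
f test	f-test
ftest	f-test
f-tests	f-test
f tests	f-test
z test	z-test
ztest	z-test
z-tests	z-test
z tests	z-test
p value	p-value
pvalue	p-value
p-values	p-value
p values	p-value
pvalues	p-value
analysis of variance	anova
analyses of variance	anova
anovas	anova
analysis of covariance	ancova
ancovas	ancova
one way	one-way
oneway	one-way
two way	two-way
twoway	two-way
wilcoxon rank sum	wilcoxon-rank-sum
wilcoxon rank-sum	wilcoxon-rank-sum
wilcoxon signed rank	wilcoxon-signed-rank
wilcoxon signed-rank	wilcoxon-signed-rank
mann whitney	mann-whitney
mann-whitney-u	mann-whitney
kruskal wallis	kruskal-wallis
kruskalwallis	kruskal-wallis
hosmer lemeshow	hosmer-lemeshow
kolmogorov smirnov	kolmogorov-smirnov
shapiro wilk	shapiro-wilk
log rank	log-rank
logrank	log-rank
log-ranks	log-rank
post hoc	post-hoc
posthoc	post-hoc
odds ratio	odds-ratio
odds-ratios	odds-ratio
odds ratios	odds-ratio
hazard ratio	hazard-ratio
hazard-ratios	hazard-ratio
hazard ratios	hazard-ratio
risk ratio	risk-ratio
risk-ratios	risk-ratio
risk ratios	risk-ratio
confidence interval	confidence-interval
confidence-intervals	confidence-interval
confidence intervals	confidence-interval
credible interval	credible-interval
credible-intervals	credible-interval
credible intervals	credible-interval
standard deviation	standard-deviation
standard-deviations	standard-deviation
standard deviations	standard-deviation
standard error	standard-error
standard-errors	standard-error
standard errors	standard-error
interquartile range	inter-quartile-range
inter-quartile range	inter-quartile-range
intention to treat	intention-to-treat
intent to treat	intention-to-treat
intent-to-treat	intention-to-treat
per protocol	per-protocol
sample size	sample-size
sample-sizes	sample-size
sample sizes	sample-size
samplesize	sample-size
effect size	effect-size
effect-sizes	effect-size
effect sizes	effect-size
mixed model	mixed-model
mixed-models	mixed-model
mixed models	mixed-model
linear mixed model	linear-mixed-model
linear mixed models	linear-mixed-model
linear mixed-model	linear-mixed-model
linear mixed-models	linear-mixed-model
repeated measures	repeated-measures
repeated-measure	repeated-measures
meta analysis	meta-analysis
metaanalysis	meta-analysis
meta-analyses	meta-analysis
meta analyses	meta-analysis
metaanalyses	meta-analysis
goodness of fit	goodness-of-fit
goodness-of-fits	goodness-of-fit
fishers exact	fisher-exact
fisher exact	fisher-exact
fisher's exact	fisher-exact
mcnemars	mcnemar
mcnemar's	mcnemar
rank sum	rank-sum
ranksum	rank-sum
signed rank	signed-rank
cox proportional hazards	cox-proportional-hazard
cox proportional hazard	cox-proportional-hazard
proportional hazards	proportional-hazard
proportional hazard	proportional-hazard
generalized estimating equations	generalized-estimating-equation
generalized estimating equation	generalized-estimating-equation
mixed effects	mixed-effects
mixed-effect	mixed-effects
random effects	random-effects
random-effect	random-effects
fixed effects	fixed-effects
fixed-effect	fixed-effects
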