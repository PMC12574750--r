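Demographic summary tables of the 200-subject clinical cohort that the
synthetic generator emulates. The severity ("ds_*", three groups derived
from HAMD-17 bands 0-7 / 8-23 / >=24; group sizes 97/30/73 as tabulated)
and risk ("sr_*", two groups derived from SAD PERSONS bands 0-3 / >=4;
group sizes 110/90) tables hold counts per demographic level; the *_age
files hold group-level mean/SD/n in years. All tests in the package run
these tables through the uncorrected Pearson chi-square or the
summary-statistic age comparisons.
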