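marker,group,in_gram_positive_sum,in_multivariate_fungi
18:1w9c,fungi,FALSE,TRUE
"18:2w6,9",fungi,FALSE,TRUE
16:1w5,amf,FALSE,TRUE
10Me16:0,actinobacteria,TRUE,FALSE
10Me17:0,actinobacteria,TRUE,FALSE
10Me18:0,actinobacteria,TRUE,FALSE
i15:0,gram_positive,TRUE,FALSE
a15:0,gram_positive,TRUE,FALSE
i16:0,gram_positive,TRUE,FALSE
i17:0,gram_positive,TRUE,FALSE
a17:0,gram_positive,TRUE,FALSE
16:1w7,gram_negative,FALSE,FALSE
cy17:0,gram_negative,FALSE,FALSE
cy19:0,gram_negative,FALSE,FALSE
18:1w9t,general,FALSE,FALSE
16:0,general,FALSE,FALSE
17:0,general,FALSE,FALSE
18:0,general,FALSE,FALSE
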