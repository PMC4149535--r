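dcm_id,panel_id,criterion,score
census,consensus,accuracy,2.33333333333333
census,consensus,relevance,8
census,consensus,consistency,5.5
census,consensus,timeliness,3
census,consensus,accessibility,5.66666666666667
NHS,consensus,accuracy,0.833333333333333
NHS,consensus,relevance,2.5
NHS,consensus,consistency,4.5
NHS,consensus,timeliness,3
NHS,consensus,accessibility,6.66666666666667
DHS,consensus,accuracy,1
DHS,consensus,relevance,4
DHS,consensus,consistency,6
DHS,consensus,timeliness,5
DHS,consensus,accessibility,7.66666666666667
CRVS,consensus,accuracy,0.333333333333333
CRVS,consensus,relevance,0.5
CRVS,consensus,consistency,4.5
CRVS,consensus,timeliness,5
CRVS,consensus,accessibility,0.666666666666667
HMS,consensus,accuracy,4.83333333333333
HMS,consensus,relevance,2.5
HMS,consensus,consistency,5
HMS,consensus,timeliness,7
HMS,consensus,accessibility,3.66666666666667
IDS,consensus,accuracy,3.16666666666667
IDS,consensus,relevance,1
IDS,consensus,consistency,5.5
IDS,consensus,timeliness,9
IDS,consensus,accessibility,4
X-DSS,consensus,accuracy,5
X-DSS,consensus,relevance,6.5
X-DSS,consensus,consistency,4.5
X-DSS,consensus,timeliness,7.5
X-DSS,consensus,accessibility,4.66666666666667
Y-DSS,consensus,accuracy,6
Y-DSS,consensus,relevance,6.5
Y-DSS,consensus,consistency,4.5
Y-DSS,consensus,timeliness,8.5
Y-DSS,consensus,accessibility,5
MM,consensus,accuracy,4.5
MM,consensus,relevance,5
MM,consensus,consistency,5.5
MM,consensus,timeliness,7.5
MM,consensus,accessibility,4
A-DSS,consensus,accuracy,5
A-DSS,consensus,relevance,4.5
A-DSS,consensus,consistency,5.5
A-DSS,consensus,timeliness,8.5
A-DSS,consensus,accessibility,5
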