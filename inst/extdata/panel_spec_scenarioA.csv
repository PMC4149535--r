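dcm_id,criterion,mean,min,max
census,accuracy,2.33333333333333,0.333333333333333,4.33333333333333
census,relevance,8,6,10
census,consistency,5.5,3.5,7.5
census,timeliness,3,1,5
census,accessibility,5.66666666666667,3.66666666666667,7.66666666666667
census,improvement,4,2,6
NHS,accuracy,0.833333333333333,0,1.66666666666667
NHS,relevance,2.5,0.5,4.5
NHS,consistency,4.5,2.5,6.5
NHS,timeliness,3,1,5
NHS,accessibility,6.66666666666667,4.66666666666667,8.66666666666667
NHS,improvement,2,0,4
DHS,accuracy,1,0,2
DHS,relevance,4,2,6
DHS,consistency,6,4,8
DHS,timeliness,5,3,7
DHS,accessibility,7.66666666666667,5.66666666666667,9.66666666666667
DHS,improvement,2,0,4
HMS,accuracy,4.83333333333333,2.83333333333333,6.83333333333333
HMS,relevance,2.5,0.5,4.5
HMS,consistency,5,3,7
HMS,timeliness,7,5,9
HMS,accessibility,3.66666666666667,1.66666666666667,5.66666666666667
HMS,improvement,8,6,10
IDS,accuracy,3.16666666666667,1.16666666666667,5.16666666666667
IDS,relevance,1,0,2
IDS,consistency,5.5,3.5,7.5
IDS,timeliness,9,8,10
IDS,accessibility,4,2,6
IDS,improvement,6,4,8
X-DSS,accuracy,5,3,7
X-DSS,relevance,6.5,4.5,8.5
X-DSS,consistency,4.5,2.5,6.5
X-DSS,timeliness,7.5,5.5,9.5
X-DSS,accessibility,4.66666666666667,2.66666666666667,6.66666666666667
X-DSS,improvement,7,5,9
Y-DSS,accuracy,6,4,8
Y-DSS,relevance,6.5,4.5,8.5
Y-DSS,consistency,4.5,2.5,6.5
Y-DSS,timeliness,8.5,7,10
Y-DSS,accessibility,5,3,7
Y-DSS,improvement,7,5,9
MM,accuracy,4.5,2.5,6.5
MM,relevance,5,3,7
MM,consistency,5.5,3.5,7.5
MM,timeliness,7.5,5.5,9.5
MM,accessibility,4,2,6
MM,improvement,6,4,8
A-DSS,accuracy,5,3,7
A-DSS,relevance,4.5,2.5,6.5
A-DSS,consistency,5.5,3.5,7.5
A-DSS,timeliness,8.5,7,10
A-DSS,accessibility,5,3,7
A-DSS,improvement,5,3,7
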