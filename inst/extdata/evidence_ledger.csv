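id,comparison,db,description
E1,Hn/Hs,3,1-client scores discriminate nonbinders better than 2-client scores
E1,Hi/Hs,3,1-client scores discriminate nonbinders better than 2-client scores
E2,Hn/Hs,6,binder 2-client scores cluster confidently while 1-client scores are bimodal
E2,Hi/Hs,6,binder 2-client scores cluster confidently while 1-client scores are bimodal
E3,Hn/Hs,-8,a sizable share of false positives are AAA mutants of strong binders
E3,Hi/Hs,6,a sizable share of false positives are AAA mutants of strong binders
E4,Hn/Hs,-2,full dataset uncorrelated with affinity but homogeneous subsets correlate
E4,Hi/Hs,22,full dataset uncorrelated with affinity but homogeneous subsets correlate
E5,Hn/Hs,0,success rates correlate with affinity only within homogeneous subsets
E5,Hi/Hs,18,success rates correlate with affinity only within homogeneous subsets
E6,Hn/Hs,-7,success-rate correlation holds at client length 14 but not 16
E6,Hi/Hs,7,success-rate correlation holds at client length 14 but not 16
E7,Hn/Hs,-17,subsets with decent R2 but no AMI relationship
E7,Hi/Hs,-4,subsets with decent R2 but no AMI relationship
E8,Hn/Hs,10,1-client scores track affinities better than 2-client scores
E8,Hi/Hs,10,1-client scores track affinities better than 2-client scores
E9,Hn/Hs,12,the best binning strategy is inconsistent across sub-datasets
E9,Hi/Hs,18,the best binning strategy is inconsistent across sub-datasets
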