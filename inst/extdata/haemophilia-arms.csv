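label,mu_hat,n0,cost
AP,0.9259,27,176397
OD,0.5517,29,56619
TP,0.7917,24,117651
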