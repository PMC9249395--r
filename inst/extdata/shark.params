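# preset: shark
label=shark
act=0.25
inh=52
deg=0.0050000000000000001
da=0.01
di=0.45000000000000001
sec=1.1000000000000001
bwi=10
bgr=0.01
bia=1
pro=0.001
n_iter=11000
seed=1
sat=0.050000000000000003
ba=0.00050000000000000001
aip=0.02
idr=3
a0=0.050000000000000003
noise=0
knot_thr=3
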