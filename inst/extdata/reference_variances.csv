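cohort,variance
healthy,0.0012
healthy,0.0030
healthy,0.0023
healthy,0.0014
healthy,0.0040
healthy,0.0025
healthy,0.0031
healthy,0.0018
unhealthy,0.0006424
unhealthy,0.0003502
unhealthy,0.0082
unhealthy,0.0015
unhealthy,0.0064
unhealthy,0.0030
unhealthy,0.0014
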