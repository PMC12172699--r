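dataset,n,measure,mean,sd,published_rv
GAAIN PiB,34,pib_std,0.00,4.41,NA
GAAIN PiB,34,pib_ns,-0.52,4.39,1.00
GAAIN PiB/FBP,13,pib_std,-0.67,2.60,NA
GAAIN PiB/FBP,13,pib_ns,2.30,3.59,1.38
GAAIN PiB/FBP,13,tracer_std,2.60,9.84,3.78
GAAIN PiB/FBP,13,tracer_ns,-0.98,12.00,4.61
GAAIN PiB/FMM,24,pib_std,-0.58,6.04,NA
GAAIN PiB/FMM,24,pib_ns,3.05,6.40,1.06
GAAIN PiB/FMM,24,tracer_std,-1.10,7.16,1.19
GAAIN PiB/FMM,24,tracer_ns,-1.72,8.22,1.36
GAAIN PiB/FBB,10,pib_std,-1.12,3.42,NA
GAAIN PiB/FBB,10,pib_ns,-0.50,3.75,1.10
GAAIN PiB/FBB,10,tracer_std,0.16,7.01,2.05
GAAIN PiB/FBB,10,tracer_ns,-3.14,5.91,1.73
GAAIN PiB/NAV,10,pib_std,-2.56,4.26,NA
GAAIN PiB/NAV,10,pib_ns,-0.36,5.23,1.23
GAAIN PiB/NAV,10,tracer_std,-2.40,4.30,1.01
GAAIN PiB/NAV,10,tracer_ns,-2.75,6.38,1.50
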