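reaction,delta_g,delta_h,minus_t_delta_s
non-catalyzed forward,16.89,0.86,16.03
non-catalyzed reverse,48.06,48.66,-0.60
beta-CD set 1 forward,22.75,21.29,1.47
beta-CD set 1 reverse,47.83,49.44,-1.61
beta-CD set 2 forward,24.12,21.14,2.98
beta-CD set 2 reverse,48.67,49.92,-1.25
dimethyl-beta-CD set 1 forward,13.73,10.05,3.68
dimethyl-beta-CD set 1 reverse,48.51,51.50,-2.99
dimethyl-beta-CD set 2 forward,19.68,20.18,-0.50
dimethyl-beta-CD set 2 reverse,49.48,51.25,-1.77
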