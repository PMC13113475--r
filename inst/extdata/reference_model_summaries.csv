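model_id,variables,term,estimate,se,t,significant,r2,rmse,resid_var
1,ME+NDF,Intercept,19.23,0.42,46.06,,0.79,1.47,2.32
1,ME+NDF,NDF,1.88,0.10,19.75,TRUE,0.79,1.47,2.32
1,ME+NDF,ME,0.31,0.10,3.22,TRUE,0.79,1.47,2.32
2,GE+NDF,Intercept,19.23,0.42,46.07,,0.79,1.47,2.32
2,GE+NDF,NDF,1.88,0.10,19.71,TRUE,0.79,1.47,2.32
2,GE+NDF,GE,0.31,0.10,3.21,TRUE,0.79,1.47,2.32
3,NDF+EE,Intercept,19.23,0.42,46.06,,0.79,1.48,2.35
3,NDF+EE,NDF,1.76,0.09,20.63,TRUE,0.79,1.48,2.35
3,NDF+EE,EE,0.16,0.09,1.84,FALSE,0.79,1.48,2.35
4,ME+NDF+FA,Intercept,19.23,0.42,46.06,,0.80,1.46,2.30
4,ME+NDF+FA,NDF,1.74,0.11,15.18,TRUE,0.80,1.46,2.30
4,ME+NDF+FA,ME,0.23,0.10,2.27,TRUE,0.80,1.46,2.30
4,ME+NDF+FA,FA,-0.18,0.08,-2.17,TRUE,0.80,1.46,2.30
5,ME+NDF+EE,Intercept,19.23,0.42,46.06,,0.79,1.47,2.31
5,ME+NDF+EE,NDF,1.88,0.10,19.78,TRUE,0.79,1.47,2.31
5,ME+NDF+EE,ME,0.44,0.15,2.85,TRUE,0.79,1.47,2.31
5,ME+NDF+EE,EE,-0.15,0.14,-1.10,FALSE,0.79,1.47,2.31
6,ME+CP+NDF,Intercept,19.23,0.42,46.06,,0.79,1.47,2.32
6,ME+CP+NDF,NDF,1.87,0.10,19.21,TRUE,0.79,1.47,2.32
6,ME+CP+NDF,ME,0.32,0.12,2.72,TRUE,0.79,1.47,2.32
6,ME+CP+NDF,CP,-0.03,0.11,-0.26,FALSE,0.79,1.47,2.32
7,GE+CP+NDF,Intercept,19.23,0.42,46.06,,0.79,1.47,2.32
7,GE+CP+NDF,NDF,1.87,0.10,19.19,TRUE,0.79,1.47,2.32
7,GE+CP+NDF,GE,0.32,0.12,2.72,TRUE,0.79,1.47,2.32
7,GE+CP+NDF,CP,-0.03,0.11,-0.26,FALSE,0.79,1.47,2.32
8,GE+NDF+FA,Intercept,19.23,0.42,46.06,,0.80,1.46,2.30
8,GE+NDF+FA,NDF,1.74,0.11,15.14,TRUE,0.80,1.46,2.30
8,GE+NDF+FA,GE,0.23,0.10,2.26,TRUE,0.80,1.46,2.30
8,GE+NDF+FA,FA,-0.20,0.08,-2.17,TRUE,0.80,1.46,2.30
9,GE+NDF+EE,Intercept,19.23,0.42,46.06,,0.79,1.47,2.31
9,GE+NDF+EE,NDF,1.88,0.10,19.75,TRUE,0.79,1.47,2.31
9,GE+NDF+EE,GE,0.44,0.15,2.84,TRUE,0.79,1.47,2.31
9,GE+NDF+EE,EE,-0.15,0.14,-1.09,FALSE,0.79,1.47,2.31
10,CP+NDF+FA+EE,Intercept,19.23,0.42,46.06,,0.80,1.46,2.30
10,CP+NDF+FA+EE,NDF,1.65,0.10,16.19,TRUE,0.80,1.46,2.30
10,CP+NDF+FA+EE,FA,-0.28,0.08,-3.32,TRUE,0.80,1.46,2.30
10,CP+NDF+FA+EE,EE,0.20,0.10,1.99,FALSE,0.80,1.46,2.30
10,CP+NDF+FA+EE,CP,-0.00,0.11,-0.02,FALSE,0.80,1.46,2.30
11,GE+CP+NDF+FA+EE,Intercept,19.23,0.42,46.06,,0.80,1.46,2.30
11,GE+CP+NDF+FA+EE,NDF,1.68,0.14,12.24,TRUE,0.80,1.46,2.30
11,GE+CP+NDF+FA+EE,FA,-0.24,0.12,-1.98,FALSE,0.80,1.46,2.30
11,GE+CP+NDF+FA+EE,GE,0.10,0.25,0.40,FALSE,0.80,1.46,2.30
11,GE+CP+NDF+FA+EE,EE,0.13,0.20,0.67,FALSE,0.80,1.46,2.30
11,GE+CP+NDF+FA+EE,CP,-0.02,0.11,-0.15,FALSE,0.80,1.46,2.30
12,ME+CP+NDF+FA+EE,Intercept,19.23,0.42,46.06,,0.80,1.46,2.30
12,ME+CP+NDF+FA+EE,NDF,1.69,0.14,12.31,TRUE,0.80,1.46,2.30
12,ME+CP+NDF+FA+EE,FA,-0.24,0.12,-1.97,FALSE,0.80,1.46,2.30
12,ME+CP+NDF+FA+EE,EE,0.13,0.20,0.65,FALSE,0.80,1.46,2.30
12,ME+CP+NDF+FA+EE,ME,0.10,0.25,0.42,FALSE,0.80,1.46,2.30
12,ME+CP+NDF+FA+EE,CP,-0.02,0.11,-0.15,FALSE,0.80,1.46,2.30
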