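roi_id,mean_amplitude,baseline_sd,ionomycin_response
roi01,5.0,1.0,12.0
roi02,4.2,1.5,9.5
roi03,1.9,1.0,8.0
roi04,6.8,2.1,15.2
roi05,0.5,0.9,7.1
roi06,3.1,1.2,10.4
roi07,2.6,1.2,6.6
roi08,1.0,2.2,11.3
roi09,7.7,3.0,14.8
roi10,2.6,1.1,9.9
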