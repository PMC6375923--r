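sample_id,tf_total,tf_sd,fl_total,fl_sd
CO-1,3890.4,96.9,1001.7,65.5
CO-2,6986.8,35.0,753.4,33.0
CO-3,4128.0,27.8,753.4,33.0
CO-4,12455.4,2.8,280.9,6.7
CO-5,9513.3,241.1,1069.6,50.6
CO-6,4994.8,130.3,2367.3,63.0
CO-7,14011.7,130.7,848.7,51.7
CO-C,12386.9,174.0,908.1,44.7
CP-1,6002.7,38.1,NA,NA
CP-2,8247.9,297.4,NA,NA
CP-3,7568.8,69.8,260.3,17.1
CP-4,7790.8,44.9,213.9,8.0
CP-C,523.3,5.9,NA,NA
CI-1,6750.1,99.9,179.1,4.5
CI-2,5605.4,275.6,227.8,20.3
CI-3,9528.8,114.2,NA,NA
CH-1,14899.2,470.9,NA,NA
CH-2,11099.6,702.3,NA,NA
CHO-C,3650.5,50.5,NA,NA
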