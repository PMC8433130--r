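center
588
679
699
757
766
878
889
1020
1080
1158
1230
1260
1380
1460
1670
1740
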