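# Synthetic end-condition table for the V-shaped repressor model.
# Joining-step parameters (deg / Angstrom) expressing the frame of the
# loop start (entry operator centre) in the frame of the loop end (exit
# operator centre), per loop orientation and opening angle dalpha.
# SYNTHETIC stand-in generated by lacr_end_condition_table(); not derived
# from crystallographic coordinates.
loop_type,dalpha,tilt,roll,twist,shift,slide,rise
A1,0,0,126.2445,41.6042,-67.6189,0,0
A1,10,0,116.9315,34.116,-80,0,0
A1,20,0,107.4518,28.3959,-91.7722,0,0
A1,30,0,97.8636,23.8428,-102.846,0,0
A1,40,0,88.2016,20.0918,-113.1371,0,0
A1,50,0,78.4875,16.9101,-122.5671,0,0
A1,60,0,68.7358,14.1421,-131.0643,0,0
A1,70,0,58.9563,11.6797,-138.5641,0,0
A1,80,0,49.1563,9.4447,-145.0092,0,0
A1,90,0,39.341,7.3785,-150.3508,0,0
A1,100,0,29.5146,5.4354,-154.5481,0,0
A1,110,0,19.6805,3.5783,-157.5692,0,0
A1,120,0,9.8414,1.7759,-159.3912,0,0
A2,0,0,126.2445,41.6042,67.6189,0,0
A2,10,0,116.9315,34.116,80,0,0
A2,20,0,107.4518,28.3959,91.7722,0,0
A2,30,0,97.8636,23.8428,102.846,0,0
A2,40,0,88.2016,20.0918,113.1371,0,0
A2,50,0,78.4875,16.9101,122.5671,0,0
A2,60,0,68.7358,14.1421,131.0643,0,0
A2,70,0,58.9563,11.6797,138.5641,0,0
A2,80,0,49.1563,9.4447,145.0092,0,0
A2,90,0,39.341,7.3785,150.3508,0,0
A2,100,0,29.5146,5.4354,154.5481,0,0
A2,110,0,19.6805,3.5783,157.5692,0,0
A2,120,0,9.8414,1.7759,159.3912,0,0
P1,0,0,-49.1563,-9.4447,0,13.1724,-66.3235
P1,10,0,-58.9563,-11.6797,0,16.2798,-78.326
P1,20,0,-68.7358,-14.1421,0,19.6961,-89.6337
P1,30,0,-78.4875,-16.9101,0,23.5253,-100.1192
P1,40,0,-88.2016,-20.0918,0,27.9099,-109.6405
P1,50,0,-97.8636,-23.8428,0,33.0511,-118.0268
P1,60,0,-107.4518,-28.3959,0,39.2436,-125.0512
P1,70,0,-116.9315,-34.116,0,46.9343,-130.3732
P1,80,0,-126.2445,-41.6042,0,56.8225,-133.4124
P1,90,0,-135.2854,-51.9066,0,70.0221,-133.0499
P1,100,0,-143.8489,-66.9409,0,88.2411,-126.8804
P1,110,0,-151.5002,-90.2678,0,113.4012,-109.3995
P1,120,0,-157.297,-127.4342,0,143.459,-69.4626
P2,0,0,-49.1563,-9.4447,0,-13.1724,66.3235
P2,10,0,-58.9563,-11.6797,0,-16.2798,78.326
P2,20,0,-68.7358,-14.1421,0,-19.6961,89.6337
P2,30,0,-78.4875,-16.9101,0,-23.5253,100.1192
P2,40,0,-88.2016,-20.0918,0,-27.9099,109.6405
P2,50,0,-97.8636,-23.8428,0,-33.0511,118.0268
P2,60,0,-107.4518,-28.3959,0,-39.2436,125.0512
P2,70,0,-116.9315,-34.116,0,-46.9343,130.3732
P2,80,0,-126.2445,-41.6042,0,-56.8225,133.4124
P2,90,0,-135.2854,-51.9066,0,-70.0221,133.0499
P2,100,0,-143.8489,-66.9409,0,-88.2411,126.8804
P2,110,0,-151.5002,-90.2678,0,-113.4012,109.3995
P2,120,0,-157.297,-127.4342,0,-143.459,69.4626
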