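pair,session,condition,trial,phase,actor,code,referent,onset,offset
FIX,1,close,1,1,dog,gaze_box,2,0.00,1.00
FIX,1,close,1,1,dog,gaze_owner,NA,2.00,2.60
FIX,1,close,1,1,dog,gaze_box,3,7.00,9.00
FIX,1,close,1,1,dog,move_owner,NA,8.00,8.60
FIX,1,close,1,1,dog,gaze_box,2,14.00,15.00
FIX,1,close,1,1,dog,vocalize,NA,16.00,16.60
FIX,1,close,1,1,dog,move_box,3,21.00,23.00
FIX,1,close,1,1,dog,gaze_owner,NA,22.00,22.60
FIX,1,close,1,1,dog,move_owner,NA,28.00,28.60
FIX,1,close,1,1,dog,move_box,2,29.60,30.60
FIX,1,close,1,1,dog,move_box,3,35.00,37.00
FIX,1,close,1,1,dog,vocalize,NA,36.00,36.60
FIX,1,close,1,1,dog,near_box,2,42.00,43.00
FIX,1,close,1,1,dog,gaze_owner,NA,44.00,44.60
FIX,1,close,1,1,dog,near_box,3,49.00,51.00
FIX,1,close,1,1,dog,move_owner,NA,50.00,50.60
FIX,1,close,1,1,dog,near_box,2,56.00,57.00
FIX,1,close,1,1,dog,vocalize,NA,58.00,58.60
FIX,1,close,1,1,dog,jump_box,3,63.00,65.00
FIX,1,close,1,1,dog,gaze_owner,NA,64.00,64.60
FIX,1,close,1,1,dog,jump_box,2,70.00,71.00
FIX,1,close,1,1,dog,move_owner,NA,72.00,72.60
FIX,1,close,1,1,dog,jump_box,3,77.00,79.00
FIX,1,close,1,1,dog,vocalize,NA,78.00,78.60
FIX,1,close,1,1,dog,open_box,2,84.00,85.00
FIX,1,close,1,1,dog,gaze_owner,NA,86.00,86.60
FIX,1,close,1,1,dog,open_box,3,91.00,93.00
FIX,1,close,1,1,dog,move_owner,NA,92.00,92.60
FIX,1,close,1,1,dog,open_box,2,98.00,99.00
FIX,1,close,1,1,dog,vocalize,NA,100.00,100.60
FIX,1,close,1,1,dog,gaze_box,1,105.00,106.00
FIX,1,close,1,1,dog,vocalize,NA,108.00,108.20
FIX,1,close,1,1,dog,gaze_box,4,112.00,113.00
FIX,1,close,1,1,dog,gaze_owner,NA,115.20,115.40
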